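# Quantitative scoring of dual electropherogram peaks at IGS diagnostic
# sites: copy-number proportion (CNP) of S-type rDNA arrays, and group
# comparisons across SINE-X genotypes.

#' A dual-peak observation at an IGS diagnostic site
#'
#' One sequencing-trace observation at a form-diagnostic IGS position (581:
#' M = T, S = C; 690: M = A, S = T).  Because the rDNA array is multicopy,
#' both channels can show signal in one individual; the relative heights
#' estimate the proportion of S-type repeats.
#'
#' @param individual_id Sample identifier.
#' @param site Diagnostic site, `581` or `690`.
#' @param h_M,h_S Raw peak heights of the M- and S-specific base channel at
#'   the site (non-negative; at least one positive).
#' @param flank_M,flank_S Reference peak heights of the same two channels at
#'   flanking called positions (default window: 5 positions each side).
#' @return An object of class `peak_observation`.
#' @export
peak_observation <- function(individual_id, site, h_M, h_S,
                             flank_M, flank_S) {
  site <- as.integer(site)
  if (!site %in% c(581L, 690L)) stop("site must be 581 or 690")
  if (h_M < 0 || h_S < 0) stop("peak heights must be non-negative")
  if (h_M == 0 && h_S == 0) stop("at least one peak height must be positive")
  structure(list(individual_id = individual_id, site = site,
                 h_M = h_M, h_S = h_S,
                 flank_M = as.numeric(flank_M),
                 flank_S = as.numeric(flank_S)),
            class = "peak_observation")
}

#' Normalize dual-peak heights against flanking positions
#'
#' Raw trace intensities vary between runs and along a trace; each channel's
#' peak height is therefore divided by the median reference height of the
#' same channel over the flanking window, making the signals comparable
#' across traces and invariant to uniform rescaling.
#'
#' @param obs A [peak_observation()].
#' @return Named numeric vector `c(s_M, s_S)` of normalized signals.
#' @export
normalize_peak_heights <- function(obs) {
  stopifnot(inherits(obs, "peak_observation"))
  if (!length(obs$flank_M) && !length(obs$flank_S))
    stop("both flanking windows are empty")
  if (!length(obs$flank_M) && obs$h_M > 0)
    stop("empty M-channel flanking window with positive M peak")
  if (!length(obs$flank_S) && obs$h_S > 0)
    stop("empty S-channel flanking window with positive S peak")
  s_M <- if (length(obs$flank_M)) obs$h_M / stats::median(obs$flank_M) else 0
  s_S <- if (length(obs$flank_S)) obs$h_S / stats::median(obs$flank_S) else 0
  c(s_M = s_M, s_S = s_S)
}

#' Copy-number proportion score
#'
#' The CNP score is the S-specific signal divided by the total signal,
#' `cnp = s_S / (s_M + s_S)`: 0 for an all-M rDNA array, 1 for all-S, about
#' 0.5 for a balanced mixed array as expected in an F1 hybrid.
#'
#' @param s_M,s_S Normalized channel signals (see
#'   [normalize_peak_heights()]).
#' @return The CNP score in `[0, 1]`, or `NA` when both signals are zero.
#' @examples
#' cnp_score(1, 0)      # 0: pure M arrays
#' cnp_score(0.5, 0.5)  # 0.5: balanced arrays
#' @export
cnp_score <- function(s_M, s_S) {
  if (any(s_M < 0) || any(s_S < 0)) stop("signals must be non-negative")
  tot <- s_M + s_S
  ifelse(tot > 0, s_S / tot, NA_real_)
}

#' Classify a CNP score into array classes
#'
#' Individuals from areas without hybridization score in `[0, 0.1]` or
#' `[0.9, 1]`, as expected when one array type is fixed; those ranges set
#' the default thresholds.
#'
#' @param cnp Numeric vector of CNP scores in `[0, 1]`.
#' @param low,high Classification thresholds, `0 <= low < high <= 1`.
#' @return Character vector: `"pure_M_like"` (`cnp <= low`), `"mixed"`, or
#'   `"pure_S_like"` (`cnp >= high`).
#' @export
classify_cnp <- function(cnp, low = 0.1, high = 0.9) {
  if (!(low >= 0 && low < high && high <= 1))
    stop("thresholds must satisfy 0 <= low < high <= 1")
  out <- rep("mixed", length(cnp))
  out[cnp <= low] <- "pure_M_like"
  out[cnp >= high] <- "pure_S_like"
  out[is.na(cnp)] <- NA_character_
  out
}

#' Compare CNP distributions across genotype groups
#'
#' Omnibus Kruskal-Wallis test (tie-corrected, df = k - 1) of CNP scores
#' across SINE-X genotype groups, followed by all pairwise Mann-Whitney
#' tests with Bonferroni correction (p multiplied by the number of pairwise
#' comparisons, capped at 1).  Group medians and quartiles are returned for
#' box-plot summaries.
#'
#' @param cnp Numeric vector of CNP scores.
#' @param group Grouping factor (e.g. SINE-X genotype), same length.
#' @param n_comparisons Number of pairwise comparisons used for the
#'   Bonferroni factor; defaults to `choose(k, 2)` for k groups, and it is
#'   an error to request a different number.
#' @return A list with `kruskal` (`statistic`, `df`, `p`), `pairwise` (data
#'   frame with raw and Bonferroni-adjusted p per pair), `summary` (per-group
#'   n, median, quartiles) and `excluded` (groups dropped for having fewer
#'   than 2 observations).
#' @export
cnp_group_compare <- function(cnp, group, n_comparisons = NULL) {
  keep <- !is.na(cnp) & !is.na(group)
  cnp <- cnp[keep]
  group <- factor(group[keep])
  sizes <- table(group)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning("excluding groups with fewer than 2 observations: ",
            paste(small, collapse = ", "))
    keep <- !(group %in% small)
    cnp <- cnp[keep]
    group <- droplevels(group[keep])
  }
  k <- nlevels(group)
  if (k < 2) stop("at least 2 non-empty groups are required")
  m <- choose(k, 2)
  if (!is.null(n_comparisons) && n_comparisons != m)
    stop(sprintf("n_comparisons (%d) must equal choose(k, 2) = %d",
                 n_comparisons, m))
  kw <- stats::kruskal.test(cnp, group)
  pairs <- utils::combn(levels(group), 2)
  pw <- apply(pairs, 2, function(pr) {
    w <- suppressWarnings(stats::wilcox.test(cnp[group == pr[1]],
                                             cnp[group == pr[2]]))
    c(p_raw = w$p.value, p_bonferroni = min(1, w$p.value * m))
  })
  pairwise <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                         t(pw), stringsAsFactors = FALSE)
  summ <- do.call(rbind, lapply(levels(group), function(g) {
    q <- stats::quantile(cnp[group == g], c(0, 0.25, 0.5, 0.75, 1))
    data.frame(group = g, n = sum(group == g), min = q[[1]], q1 = q[[2]],
               median = q[[3]], q3 = q[[4]], max = q[[5]],
               stringsAsFactors = FALSE)
  }))
  list(kruskal = list(statistic = unname(kw$statistic),
                      df = as.integer(unname(kw$parameter)),
                      p = kw$p.value),
       pairwise = pairwise, summary = summ, excluded = small)
}
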