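# Joint-genotype classification (parental / assorted / congruent; IGS-vs-SINE
# mismatch taxonomy) and contingency-table testing.

#' Classify a two-locus joint genotype
#'
#' Joint X-locus/3L genotypes are grouped into the classes used to describe
#' hybrid-zone structure: `parental_M` (MM/MM), `parental_S` (SS/SS),
#' `f1_like` (MS/MS, the double heterozygote expected in first-generation
#' hybrids) and `assorted` (the six remaining combinations, which require
#' recombination or backcrossing).  A genotype is `congruent` when both loci
#' carry the same genotype (the three non-assorted classes).
#'
#' @param gX,g3L Character vectors of genotype calls (`"MM"`, `"MS"`,
#'   `"SS"`); recycled to a common length.
#' @return A data frame with columns `value` (class label, `NA` for missing
#'   or ambiguous calls) and `congruent` (logical).
#' @examples
#' classify_joint_genotype(c("MM", "MS", "MM"), c("MM", "MS", "SS"))
#' @export
classify_joint_genotype <- function(gX, g3L) {
  k <- max(length(gX), length(g3L))
  gX <- rep_len(gX, k)
  g3L <- rep_len(g3L, k)
  ok <- gX %in% .geno_levels & g3L %in% .geno_levels
  value <- rep(NA_character_, k)
  value[ok & gX == "MM" & g3L == "MM"] <- "parental_M"
  value[ok & gX == "SS" & g3L == "SS"] <- "parental_S"
  value[ok & gX == "MS" & g3L == "MS"] <- "f1_like"
  value[ok & is.na(value)] <- "assorted"
  data.frame(value = value,
             congruent = ifelse(is.na(value), NA, value != "assorted"),
             stringsAsFactors = FALSE)
}

#' Classify IGS-versus-SINE genotype mismatches
#'
#' The IGS rDNA assay types an individual as pure M, pure S or M/S hybrid;
#' the SINE insertion assay gives an ordinary diploid genotype.  Because both
#' markers are X-linked and tightly associated outside hybrid zones, a
#' disagreement between them is diagnostic: type 1 (`pure_IGS_het_SINE`) --
#' IGS pure M or pure S with a heterozygous SINE genotype; type 2
#' (`hybrid_IGS_hom_SINE`) -- IGS hybrid with a homozygous SINE genotype;
#' and the rare `opposing_homozygote` (IGS pure M with SINE SS or vice
#' versa), indicative of a mixed rDNA array dominated by the opposite form.
#'
#' @param igs Character vector of IGS form calls: `"M"`, `"S"` or `"MS"`
#'   (hybrid pattern).
#' @param sine Character vector of SINE genotype calls (`"MM"`, `"MS"`,
#'   `"SS"`).
#' @return Character vector of mismatch classes (`"concordant"`,
#'   `"pure_IGS_het_SINE"`, `"hybrid_IGS_hom_SINE"`,
#'   `"opposing_homozygote"`).
#' @examples
#' mismatch_classify(c("M", "MS", "M"), c("MS", "SS", "SS"))
#' @export
mismatch_classify <- function(igs, sine) {
  k <- max(length(igs), length(sine))
  igs <- rep_len(igs, k)
  sine <- rep_len(sine, k)
  if (!all(igs %in% c("M", "S", "MS")))
    stop("igs calls must be 'M', 'S' or 'MS'")
  if (!all(sine %in% .geno_levels))
    stop("sine calls must be 'MM', 'MS' or 'SS'")
  out <- character(k)
  conc <- (igs == "M" & sine == "MM") | (igs == "S" & sine == "SS") |
    (igs == "MS" & sine == "MS")
  out[conc] <- "concordant"
  out[igs %in% c("M", "S") & sine == "MS"] <- "pure_IGS_het_SINE"
  out[igs == "MS" & sine %in% c("MM", "SS")] <- "hybrid_IGS_hom_SINE"
  out[(igs == "M" & sine == "SS") | (igs == "S" & sine == "MM")] <-
    "opposing_homozygote"
  out
}

#' Pearson chi-square test for a contingency table
#'
#' Thin, policy-carrying wrapper around [stats::chisq.test()].  Under
#' `yates = "auto"` (default) the Yates continuity correction is applied if
#' and only if the table is 2x2, the convention of common web calculators
#' and of `chisq.test()` itself.
#'
#' @param table Integer matrix of observed counts.
#' @param yates `"auto"`, `"on"` or `"off"`.  (`"on"` only affects 2x2
#'   tables, where the correction is defined.)
#' @return A list of class `assoc_test`: `chi2`, `df`, `p`, `yates`
#'   (logical, as applied), `table`, `expected`, and `warning` (message when
#'   any expected cell is below 1, else `NULL`).
#' @examples
#' contingency_chisq(matrix(c(63, 10, 45, 131), 2, byrow = TRUE))$chi2  # 75.0
#' @export
contingency_chisq <- function(table, yates = c("auto", "on", "off")) {
  yates <- match.arg(yates)
  table <- as.matrix(table)
  if (any(table < 0) || any(is.na(table)))
    stop("contingency table must contain non-negative counts")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("contingency table has a zero margin")
  correct <- switch(yates,
                    auto = all(dim(table) == 2L),
                    on   = all(dim(table) == 2L),
                    off  = FALSE)
  res <- suppressWarnings(stats::chisq.test(table, correct = correct))
  warn <- if (any(res$expected < 1))
    "some expected cell counts are below 1; the asymptotic p is unreliable"
  structure(list(chi2 = unname(res$statistic),
                 df = as.integer(unname(res$parameter)),
                 p = res$p.value, yates = correct, table = table,
                 expected = res$expected, warning = warn),
            class = "assoc_test")
}

#' @export
print.assoc_test <- function(x, ...) {
  cat(sprintf("chi-square = %.3f, df = %d, p = %.4g%s\n",
              x$chi2, x$df, x$p,
              if (x$yates) " (Yates-corrected)" else ""))
  if (!is.null(x$warning)) cat("note:", x$warning, "\n")
  invisible(x)
}

# Counts of the nine joint genotype classes from a joint_counts table.
.class_counts <- function(n) {
  n <- unclass(as.matrix(n))
  c(parental_M = n[1, 1], parental_S = n[3, 3], f1_like = n[2, 2],
    assorted = sum(n) - n[1, 1] - n[3, 3] - n[2, 2])
}

#' Joint-genotype class summary and standard association tests
#'
#' For each population sample (one [joint_counts()] table per group, e.g.
#' per country) this emits the class frequencies (parental, F1-like,
#' assorted, congruent), the M-side and S-side parental:assorted ratios
#' (parental MM/MM over assorted MM/MS + MM/SS, and SS/SS over SS/MS +
#' SS/MM), and the standard contingency tests: (i) within each group,
#' independence of the X and 3L genotypes (optionally dropping the X-MS row
#' where that class is too small to contribute), (ii) across groups,
#' congruent-vs-not by group, and (iii) within each group,
#' parental-vs-assorted by form side (M vs S), all through
#' [contingency_chisq()] with the `yates = "auto"` policy.
#'
#' @param groups A named list of `joint_counts` tables (or a single table).
#' @param drop_x_het Character vector of group names for which the
#'   independence test excludes the X-heterozygote row (used when the MS
#'   subsample is too small for a 3x3 test).
#' @return A list with `per_group` (data frame of class frequencies and
#'   ratios; ratios are `NA` when the assorted denominator is zero),
#'   `independence` (per-group `assoc_test`s), `parental_vs_assorted`
#'   (per-group 2x2 `assoc_test`s) and, when more than one group is given,
#'   `congruent_by_group` (2xK `assoc_test`).
#' @export
genotype_class_summary <- function(groups, drop_x_het = character()) {
  if (inherits(groups, "joint_counts")) groups <- list(sample = groups)
  if (is.null(names(groups)) || any(names(groups) == ""))
    stop("groups must be a named list of joint_counts tables")
  per <- lapply(names(groups), function(g) {
    n <- unclass(as.matrix(groups[[g]]))
    N <- sum(n)
    cl <- .class_counts(n)
    m_assort <- n[1, 2] + n[1, 3]
    s_assort <- n[3, 2] + n[3, 1]
    data.frame(
      group = g, N = N,
      parental_M = cl[["parental_M"]] / N,
      parental_S = cl[["parental_S"]] / N,
      f1_like = cl[["f1_like"]] / N,
      assorted = cl[["assorted"]] / N,
      parental = (cl[["parental_M"]] + cl[["parental_S"]]) / N,
      congruent = (cl[["parental_M"]] + cl[["parental_S"]] +
                     cl[["f1_like"]]) / N,
      m_ratio = if (m_assort > 0) n[1, 1] / m_assort else NA_real_,
      s_ratio = if (s_assort > 0) n[3, 3] / s_assort else NA_real_,
      m_ratio_label = if (m_assort > 0)
        sprintf("%.1f to 1 (%d/%d)", n[1, 1] / m_assort, n[1, 1], m_assort)
        else NA_character_,
      s_ratio_label = if (s_assort > 0)
        sprintf("%.1f to 1 (%d/%d)", n[3, 3] / s_assort, n[3, 3], s_assort)
        else NA_character_,
      stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  independence <- lapply(names(groups), function(g) {
    n <- unclass(as.matrix(groups[[g]]))
    if (g %in% drop_x_het) n <- n[c(1, 3), , drop = FALSE]
    keep_col <- colSums(n) > 0
    keep_row <- rowSums(n) > 0
    n <- n[keep_row, keep_col, drop = FALSE]
    if (any(dim(n) < 2)) return(NULL)
    contingency_chisq(n, yates = "auto")
  })
  names(independence) <- names(groups)
  pva <- lapply(names(groups), function(g) {
    n <- unclass(as.matrix(groups[[g]]))
    tab <- rbind(M = c(parental = n[1, 1], assorted = n[1, 2] + n[1, 3]),
                 S = c(parental = n[3, 3], assorted = n[3, 2] + n[3, 1]))
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(NULL)
    contingency_chisq(tab, yates = "auto")
  })
  names(pva) <- names(groups)
  out <- list(per_group = per, independence = independence,
              parental_vs_assorted = pva)
  if (length(groups) > 1) {
    cong <- vapply(groups, function(j) {
      cl <- .class_counts(j)
      c(sum(cl[c("parental_M", "parental_S", "f1_like")]), cl[["assorted"]])
    }, numeric(2))
    out$congruent_by_group <- contingency_chisq(t(cong), yates = "auto")
  }
  out
}
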