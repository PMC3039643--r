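# Single-locus statistics: allele frequencies, unbiased expected
# heterozygosity, Weir-Cockerham within-sample inbreeding coefficient, and
# exact Hardy-Weinberg tests by complete enumeration of the Levene
# conditional distribution.

.as_locus_counts <- function(c) {
  if (inherits(c, "locus_counts")) return(c)
  if (is.numeric(c) && length(c) == 3L) return(locus_counts(c[1], c[2], c[3]))
  stop("expected a locus_counts object or a 3-vector of genotype counts")
}

#' M-allele frequency from genotype counts
#'
#' @param c A [locus_counts()] object (or 3-vector of MM/MS/SS counts).
#' @return A list with `p_M` (frequency of the M allele) and `q_S = 1 - p_M`.
#' @examples
#' allele_frequencies(locus_counts(58, 3, 40))  # p_M = 119/202
#' @export
allele_frequencies <- function(c) {
  c <- .as_locus_counts(c)
  N <- attr(c, "N")
  p <- (2 * c[["MM"]] + c[["MS"]]) / (2 * N)
  list(p_M = p, q_S = 1 - p)
}

#' Unbiased expected heterozygosity
#'
#' Nei's expected heterozygosity with the small-sample correction,
#' `H_exp = 2 p q * 2N / (2N - 1)`, the convention used by standard
#' population-genetics software when reporting per-sample gene diversity.
#'
#' @inheritParams allele_frequencies
#' @return Expected heterozygosity in `[0, 1]`.
#' @examples
#' expected_heterozygosity(locus_counts(58, 3, 40))  # 0.4865
#' @export
expected_heterozygosity <- function(c) {
  c <- .as_locus_counts(c)
  N <- attr(c, "N")
  if (N <= 1) stop("expected heterozygosity requires N > 1")
  p <- allele_frequencies(c)$p_M
  2 * p * (1 - p) * 2 * N / (2 * N - 1)
}

#' Weir-Cockerham within-sample inbreeding coefficient
#'
#' Single-locus, single-sample estimate of f (F_IS) from the Weir-Cockerham
#' variance components.  With n individuals, observed heterozygote proportion
#' h and allele frequency p:
#' `b = n/(n-1) * (p(1-p) - h(2n-1)/(4n))`, `c = h/2`, `f = 1 - c/(b + c)`.
#' Positive values indicate a heterozygote deficit (inbreeding, assortative
#' mating, or a Wahlund effect from pooled differentiated gene pools);
#' negative values an excess.
#'
#' @inheritParams allele_frequencies
#' @return The estimate of f, or `NA` with attribute `reason = "fixed"` when
#'   the locus is monomorphic in the sample (conventionally printed "--").
#' @examples
#' fis_weir_cockerham(locus_counts(58, 3, 40))   #  0.939
#' fis_weir_cockerham(locus_counts(23, 21, 0))   # -0.303
#' @export
fis_weir_cockerham <- function(c) {
  c <- .as_locus_counts(c)
  n <- attr(c, "N")
  if (n <= 1) stop("f estimation requires N > 1")
  p <- allele_frequencies(c)$p_M
  if (p == 0 || p == 1)
    return(structure(NA_real_, reason = "fixed"))
  h <- c[["MS"]] / n
  b <- n / (n - 1) * (p * (1 - p) - h * (2 * n - 1) / (4 * n))
  cc <- h / 2
  1 - cc / (b + cc)
}

# Levene conditional distribution of the heterozygote count given the allele
# counts (n1 M alleles, n2 S alleles in 2N genes):
#   P(n12) = N! 2^n12 n1! n2! / (n11! n12! n22! (2N)!)
# Support: n12 ranges over the parity of n1 from max(0, n1 - 2*floor(n1/2)...)
# in steps of 2 up to min(n1, n2).  Returned on the log scale.
.levene_distribution <- function(n1, n2) {
  N <- (n1 + n2) / 2
  supp <- seq.int(n1 %% 2, min(n1, n2), by = 2L)
  logp <- vapply(supp, function(h) {
    a <- (n1 - h) / 2
    b <- (n2 - h) / 2
    lfactorial(N) + h * log(2) + lfactorial(n1) + lfactorial(n2) -
      lfactorial(a) - lfactorial(h) - lfactorial(b) - lfactorial(2 * N)
  }, numeric(1))
  list(support = supp, logp = logp, p = exp(logp))
}

#' Exact Hardy-Weinberg test for a biallelic locus
#'
#' Complete enumeration of the Levene conditional distribution of the
#' heterozygote count given the observed allele counts.  The two-sided
#' p-value sums the probability of all outcomes no more probable than the
#' observed one (probability-mass convention); the one-sided alternatives sum
#' the heterozygote-deficit (`n_MS <=` observed) or -excess tail.  For a
#' biallelic locus the support is small, so full enumeration is exact and a
#' Markov chain is unnecessary; `method = "mcmc"` provides an independent
#' Metropolis sampler over the same conditional distribution as a
#' Monte-Carlo cross-check.
#'
#' @inheritParams allele_frequencies
#' @param alternative `"two_sided"` (default), `"deficit"` or `"excess"`.
#' @param method `"enumeration"` (exact, default) or `"mcmc"`.
#' @param chain_length,dememorization Markov-chain settings for
#'   `method = "mcmc"`.
#' @param seed Optional integer seed for the MCMC mode.
#' @return A list of class `hwe_test` with elements `p_value`, `alternative`,
#'   `method`, `p_obs` (probability of the observed table) and, for the
#'   enumeration method, the full `support` and `prob` vectors.  For a
#'   monomorphic locus, `p_value` is `NA` with `reason = "fixed"`.
#' @examples
#' hwe_exact_test(locus_counts(2, 0, 2))$p_value            # 0.0857
#' hwe_exact_test(locus_counts(58, 3, 40), "deficit")$p_value
#' @export
hwe_exact_test <- function(c, alternative = c("two_sided", "deficit", "excess"),
                           method = c("enumeration", "mcmc"),
                           chain_length = 100000, dememorization = 1000,
                           seed = NULL) {
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  c <- .as_locus_counts(c)
  n1 <- 2 * c[["MM"]] + c[["MS"]]
  n2 <- 2 * c[["SS"]] + c[["MS"]]
  if (n1 == 0 || n2 == 0)
    return(structure(list(p_value = NA_real_, alternative = alternative,
                          method = method, reason = "fixed"),
                     class = "hwe_test"))
  dist <- .levene_distribution(n1, n2)
  obs <- c[["MS"]]
  p_obs <- dist$p[dist$support == obs]
  if (method == "enumeration") {
    p <- switch(alternative,
      two_sided = sum(dist$p[dist$p <= p_obs * (1 + 1e-12)]),
      deficit   = sum(dist$p[dist$support <= obs]),
      excess    = sum(dist$p[dist$support >= obs]))
    return(structure(list(p_value = min(p, 1), alternative = alternative,
                          method = method, p_obs = p_obs,
                          support = dist$support, prob = dist$p),
                     class = "hwe_test"))
  }
  # Metropolis chain on the heterozygote count: propose +/-2, accept with the
  # conditional probability ratio computed pointwise (no enumeration used).
  ratio <- function(h_to, h_from) {
    # P(h_to)/P(h_from) for h_to = h_from + 2 or h_from - 2
    if (h_to > h_from) {
      a <- (n1 - h_from) / 2; b <- (n2 - h_from) / 2
      4 * a * b / ((h_from + 1) * (h_from + 2))
    } else {
      a <- (n1 - h_from) / 2; b <- (n2 - h_from) / 2
      h_from * (h_from - 1) / (4 * (a + 1) * (b + 1))
    }
  }
  run <- function() {
    h <- obs
    hits <- 0L
    lo <- n1 %% 2
    hi <- min(n1, n2)
    for (step in seq_len(dememorization + chain_length)) {
      prop <- h + sample(c(-2L, 2L), 1L)
      if (prop >= lo && prop <= hi && stats::runif(1) < ratio(prop, h))
        h <- prop
      if (step > dememorization) {
        inside <- switch(alternative,
          two_sided = dist$p[dist$support == h] <= p_obs * (1 + 1e-12),
          deficit   = h <= obs,
          excess    = h >= obs)
        if (inside) hits <- hits + 1L
      }
    }
    hits / chain_length
  }
  p <- if (is.null(seed)) run() else with_seed(seed, run())
  structure(list(p_value = p, alternative = alternative, method = method,
                 p_obs = p_obs, chain_length = chain_length, seed = seed),
            class = "hwe_test")
}

#' @export
print.hwe_test <- function(x, ...) {
  cat("Exact Hardy-Weinberg test (", x$method, ", ", x$alternative, ")\n",
      sep = "")
  if (!is.null(x$reason)) cat("not testable: locus", x$reason, "\n")
  else cat("p =", format(x$p_value, digits = 4), "\n")
  invisible(x)
}

#' Full per-locus statistics for one sample
#'
#' @inheritParams allele_frequencies
#' @return A one-row data frame with `N`, `p_M`, `H_obs`, `H_exp`, `f_is`,
#'   `hwe_p_two_sided`, `hwe_p_deficit` and `status` (`"ok"` or `"fixed"`).
#' @export
locus_stats <- function(c) {
  c <- .as_locus_counts(c)
  N <- attr(c, "N")
  p <- allele_frequencies(c)$p_M
  fixed <- p == 0 || p == 1
  data.frame(
    N = N,
    p_M = p,
    H_obs = c[["MS"]] / N,
    H_exp = if (fixed) 0 else expected_heterozygosity(c),
    f_is = if (fixed) NA_real_ else as.numeric(fis_weir_cockerham(c)),
    hwe_p_two_sided = if (fixed) NA_real_ else
      hwe_exact_test(c, "two_sided")$p_value,
    hwe_p_deficit = if (fixed) NA_real_ else
      hwe_exact_test(c, "deficit")$p_value,
    status = if (fixed) "fixed" else "ok",
    stringsAsFactors = FALSE
  )
}
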