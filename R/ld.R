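# Two-locus gametic-phase inference (EM) and linkage-disequilibrium testing
# between physically unlinked diagnostic loci.

# Constant gamete contributions of the eight phase-unambiguous genotype
# cells, plus the double-heterozygote count d whose 2N gametes split between
# cis (MM + SS) and trans (MS + SM) resolutions.
.gamete_decomposition <- function(n) {
  list(
    k = c(MM = 2 * n[1, 1] + n[1, 2] + n[2, 1],
          MS = n[1, 2] + 2 * n[1, 3] + n[2, 3],
          SM = n[2, 1] + 2 * n[3, 1] + n[3, 2],
          SS = n[2, 3] + n[3, 2] + 2 * n[3, 3]),
    d = n[2, 2]
  )
}

# Multinomial genotype log-likelihood given gamete frequencies f
# (order MM, MS, SM, SS; first index X allele, second 3L allele).
.joint_loglik <- function(f, n) {
  P <- matrix(c(f[1]^2,       2 * f[1] * f[2],                 f[2]^2,
                2 * f[1] * f[3], 2 * f[1] * f[4] + 2 * f[2] * f[3], 2 * f[2] * f[4],
                f[3]^2,       2 * f[3] * f[4],                 f[4]^2),
              3, 3, byrow = TRUE)
  use <- n > 0
  if (any(P[use] <= 0)) return(-Inf)
  sum(n[use] * log(P[use]))
}

# Marginal allele frequencies (M allele at each locus) from a 3x3 table.
.joint_margins <- function(n) {
  N <- sum(n)
  pX <- (2 * sum(n[1, ]) + sum(n[2, ])) / (2 * N)
  pL <- (2 * sum(n[, 1]) + sum(n[, 2])) / (2 * N)
  c(pX = pX, pL = pL)
}

#' EM estimation of two-locus haplotype frequencies
#'
#' Maximum-likelihood gamete (haplotype) frequencies from unphased two-locus
#' diploid genotype counts.  For two biallelic loci only the double
#' heterozygote is phase-ambiguous: the E-step splits each such individual
#' between the cis (M-M + S-S) and trans (M-S + S-M) resolutions with
#' posterior weight `f_MM f_SS / (f_MM f_SS + f_MS f_SM)`, and the M-step
#' re-estimates the four frequencies from the expected gamete counts.
#' Frequencies are initialized at linkage-equilibrium products of the sample
#' allele frequencies; the log-likelihood is non-decreasing across
#' iterations.
#'
#' @param j A [joint_counts()] object (or plain 3x3 count matrix, rows =
#'   X-locus genotype MM/MS/SS, columns = 3L genotype).
#' @param tol Stop when the log-likelihood improves by less than this
#'   (default `1e-10`).
#' @param max_iter Iteration cap (default 1000).
#' @return A list of class `hap_estimate`: `f` (named gamete frequencies
#'   `MM`, `MS`, `SM`, `SS`), `logL`, `n_iter`, `converged`,
#'   `non_identifiable` (`TRUE` when the sample consists solely of double
#'   heterozygotes, whose likelihood is invariant to a cis/trans swap),
#'   `posterior_cis` (final E-step weight) and the input `counts`.
#' @examples
#' j <- joint_counts_from_frequencies(
#'   c(0.515, 0.309, 0.010, 0.052, 0, 0.010, 0.000, 0.093, 0.010), 97)
#' em_haplotypes(j)$f  # ~ (0.5515, 0.0258, 0.0619, 0.3608)
#' @export
em_haplotypes <- function(j, tol = 1e-10, max_iter = 1000) {
  n <- unclass(as.matrix(j))
  if (!all(dim(n) == c(3, 3))) stop("j must be a 3x3 genotype count table")
  N <- sum(n)
  if (N <= 0) stop("empty table")
  dec <- .gamete_decomposition(n)
  non_ident <- dec$d == N
  m <- .joint_margins(n)
  f <- c(MM = m[["pX"]] * m[["pL"]],
         MS = m[["pX"]] * (1 - m[["pL"]]),
         SM = (1 - m[["pX"]]) * m[["pL"]],
         SS = (1 - m[["pX"]]) * (1 - m[["pL"]]))
  logL <- .joint_loglik(f, n)
  if (dec$d == 0) {
    return(structure(list(f = dec$k / (2 * N), logL = .joint_loglik(dec$k / (2 * N), n),
                          n_iter = 1L, converged = TRUE,
                          non_identifiable = FALSE, posterior_cis = NA_real_,
                          counts = n),
                     class = "hap_estimate"))
  }
  w <- NA_real_
  iter <- 0L
  converged <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    denom <- f[["MM"]] * f[["SS"]] + f[["MS"]] * f[["SM"]]
    w <- if (denom > 0) f[["MM"]] * f[["SS"]] / denom else 0.5
    exp_gam <- dec$k + dec$d * c(w, 1 - w, 1 - w, w)
    f_new <- exp_gam / (2 * N)
    names(f_new) <- names(dec$k)
    logL_new <- .joint_loglik(f_new, n)
    if (logL_new < logL - 1e-9)
      stop("EM log-likelihood decreased; this is a bug")
    improved <- logL_new - logL
    f <- f_new
    logL <- logL_new
    if (improved < tol) {
      converged <- TRUE
      break
    }
  }
  structure(list(f = f, logL = logL, n_iter = iter, converged = converged,
                 non_identifiable = non_ident, posterior_cis = w, counts = n),
            class = "hap_estimate")
}

#' @export
print.hap_estimate <- function(x, ...) {
  cat("EM haplotype frequency estimate (", x$n_iter, " iterations, logL = ",
      format(x$logL, digits = 8), ")\n", sep = "")
  print(round(x$f, 4))
  if (x$non_identifiable)
    cat("warning: phase non-identifiable (all double heterozygotes)\n")
  invisible(x)
}

#' Linkage-disequilibrium statistics from gamete frequencies
#'
#' Standard gametic disequilibrium measures: `D = f_MM - p_X p_3L`, `D'` (D
#' normalized by its bound given the allele frequencies) and
#' `r2 = D^2 / (p_X q_X p_3L q_3L)`, the squared gametic correlation.
#'
#' @param h A `hap_estimate` from [em_haplotypes()], or a 4-vector of gamete
#'   frequencies in the order MM, MS, SM, SS.
#' @return A list with `D`, `D_prime`, `r2`, `p_X`, `p_3L`.
#' @examples
#' ld_statistics(c(0.5, 0, 0, 0.5))  # D = 0.25, D' = 1, r2 = 1
#' @export
ld_statistics <- function(h) {
  f <- if (inherits(h, "hap_estimate")) h$f else h
  if (length(f) != 4L || any(f < -1e-12) || abs(sum(f) - 1) > 1e-6)
    stop("gamete frequencies must be a 4-vector summing to 1")
  pX <- f[[1]] + f[[2]]
  pL <- f[[1]] + f[[3]]
  if (pX <= 0 || pX >= 1 || pL <= 0 || pL >= 1)
    stop("monomorphic margin: LD undefined")
  D <- f[[1]] - pX * pL
  Dmax <- if (D >= 0) min(pX * (1 - pL), (1 - pX) * pL)
          else        min(pX * pL, (1 - pX) * (1 - pL))
  list(D = D,
       D_prime = if (Dmax > 0) D / Dmax else 0,
       r2 = D^2 / (pX * (1 - pX) * pL * (1 - pL)),
       p_X = pX, p_3L = pL)
}

# Expand a 3x3 joint genotype table into per-individual genotype index pairs.
.expand_joint <- function(n) {
  idx <- which(n > 0, arr.ind = TRUE)
  gx <- rep(idx[, 1], n[idx])
  gy <- rep(idx[, 2], n[idx])
  cbind(gx, gy)
}

#' Bootstrap standard deviations of EM haplotype frequencies
#'
#' Resamples N individuals with replacement, reruns [em_haplotypes()] on each
#' replicate, and reports the per-frequency standard deviation.  Replicates
#' in which either locus becomes monomorphic carry no LD information and are
#' dropped (their number is reported).
#'
#' @inheritParams em_haplotypes
#' @param B Number of bootstrap replicates (at least 100).
#' @param seed Integer seed; results are reproducible given the seed.
#' @return A list with `sd` (named 4-vector), `B`, `n_dropped`, `seed` and
#'   the matrix of replicate frequencies.
#' @export
bootstrap_haplotype_sd <- function(j, B = 500, seed = 1) {
  if (B < 100) stop("B must be at least 100")
  n <- unclass(as.matrix(j))
  N <- sum(n)
  ind <- .expand_joint(n)
  run <- function() {
    reps <- matrix(NA_real_, B, 4,
                   dimnames = list(NULL, c("MM", "MS", "SM", "SS")))
    dropped <- 0L
    for (b in seq_len(B)) {
      take <- sample.int(N, N, replace = TRUE)
      tab <- matrix(0L, 3, 3)
      for (i in take) tab[ind[i, 1], ind[i, 2]] <- tab[ind[i, 1], ind[i, 2]] + 1L
      mar <- .joint_margins(tab)
      if (any(mar <= 0) || any(mar >= 1)) {
        dropped <- dropped + 1L
        next
      }
      reps[b, ] <- em_haplotypes(tab)$f
    }
    list(sd = apply(reps, 2, stats::sd, na.rm = TRUE), B = B,
         n_dropped = dropped, seed = seed, replicates = reps)
  }
  with_seed(seed, run())
}

#' Likelihood-ratio test of two-locus association (gametic phase unknown)
#'
#' Compares the maximized multinomial genotype likelihood when gamete
#' frequencies are free ([em_haplotypes()]) against the likelihood with
#' gamete frequencies constrained to products of the sample allele
#' frequencies (no association between loci; random union of gametes within
#' each locus is assumed in both models).  Significance is assessed by a
#' permutation null that reassigns one locus's genotypes across individuals
#' -- preserving both single-locus genotype distributions while destroying
#' any inter-locus association -- implemented by drawing contingency tables
#' with fixed margins ([stats::r2dtable()], Patefield's algorithm, which is
#' exactly the permutation distribution).  The asymptotic chi-square
#' reference (df = 1) is reported alongside.
#'
#' @inheritParams em_haplotypes
#' @param n_perm Number of permutations (default 10000; fewer than 100 draws
#'   a warning).
#' @param seed Integer seed.
#' @return A list of class `lr_result`: `G` (the statistic, clamped at 0),
#'   `p_perm`, `p_chi2`, `n_perm`, `seed`, `logL_alt`, `logL_null`.  When
#'   either locus is monomorphic the result carries `reason = "fixed"` and
#'   `NA` p-values.
#' @export
lr_test_association <- function(j, n_perm = 10000, seed = 1) {
  n <- unclass(as.matrix(j))
  mar <- .joint_margins(n)
  if (any(mar <= 0) || any(mar >= 1))
    return(structure(list(G = NA_real_, p_perm = NA_real_, p_chi2 = NA_real_,
                          n_perm = n_perm, seed = seed, reason = "fixed"),
                     class = "lr_result"))
  if (n_perm < 100) warning("n_perm < 100 gives a very coarse p-value")
  G_of <- function(tab) {
    alt <- em_haplotypes(tab, tol = 1e-10, max_iter = 1000)
    m <- .joint_margins(tab)
    f0 <- c(m[["pX"]] * m[["pL"]], m[["pX"]] * (1 - m[["pL"]]),
            (1 - m[["pX"]]) * m[["pL"]], (1 - m[["pX"]]) * (1 - m[["pL"]]))
    list(G = max(0, 2 * (alt$logL - .joint_loglik(f0, tab))),
         logL_alt = alt$logL, logL_null = .joint_loglik(f0, tab))
  }
  obs <- G_of(n)
  run <- function() {
    perms <- stats::r2dtable(n_perm, rowSums(n), colSums(n))
    exceed <- 0L
    for (tab in perms)
      if (G_of(tab)$G >= obs$G - 1e-9) exceed <- exceed + 1L
    (1 + exceed) / (n_perm + 1)
  }
  p_perm <- with_seed(seed, run())
  structure(list(G = obs$G, p_perm = p_perm,
                 p_chi2 = stats::pchisq(obs$G, df = 1, lower.tail = FALSE),
                 n_perm = n_perm, seed = seed,
                 logL_alt = obs$logL_alt, logL_null = obs$logL_null),
            class = "lr_result")
}

#' @export
print.lr_result <- function(x, ...) {
  if (!is.null(x$reason)) {
    cat("LR association test: not testable (locus", x$reason, ")\n")
  } else {
    cat("LR association test: G =", format(x$G, digits = 5),
        "; permutation p =", format(x$p_perm, digits = 4),
        "(", x$n_perm, "permutations, seed", x$seed, ")",
        "; chi-square p =", format(x$p_chi2, digits = 4), "\n")
  }
  invisible(x)
}

#' Phase-resolved exact test of gametic association
#'
#' Resolves each double heterozygote to its maximum-posterior phase under the
#' EM estimate, forms the 2x2 table of gamete counts (X allele by 3L allele),
#' and applies Fisher's exact test with all margins fixed.  This is a
#' deterministic phase-known companion to the phase-unknown likelihood-ratio
#' test.
#'
#' @inheritParams em_haplotypes
#' @return A list with `p_value`, the 2x2 `gamete_table`, and the phase
#'   `resolution` applied to double heterozygotes (`"cis"` or `"trans"`).
#'   `NULL` p-value when the phase is non-identifiable.
#' @export
phase_known_exact_test <- function(j) {
  n <- unclass(as.matrix(j))
  est <- em_haplotypes(n)
  if (est$non_identifiable)
    return(list(p_value = NULL, gamete_table = NULL,
                reason = "non-identifiable phase"))
  dec <- .gamete_decomposition(n)
  cis <- is.na(est$posterior_cis) || est$posterior_cis >= 0.5
  gam <- dec$k + dec$d * if (cis) c(1, 0, 0, 1) else c(0, 1, 1, 0)
  tab <- matrix(gam, 2, 2, byrow = TRUE,
                dimnames = list(X = c("M", "S"), L3 = c("M", "S")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("degenerate gamete table: empty margin")
  list(p_value = stats::fisher.test(tab)$p.value,
       gamete_table = tab,
       resolution = if (cis) "cis" else "trans")
}
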