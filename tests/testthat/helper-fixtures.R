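# Reconstructed integer-count fixtures from the packaged survey frequency
# tables, shared across test files.

survey <- load_survey_tables()

survey_locus <- function(table, sample) {
  df <- survey[[table]]
  row <- df[df$sample == sample, ]
  cnt <- counts_from_frequencies(row$freq[[1]], row$N)
  locus_counts(cnt[1], cnt[2], cnt[3])
}

survey_joint <- function(sample, country = NULL) {
  df <- survey$joint_x_3l
  row <- if (is.null(country)) df[df$sample == sample, ]
         else df[df$sample == sample & df$country == country, ]
  joint_counts_from_frequencies(row$freq[[1]], row$N)
}

# Independent maximizer of the two-locus genotype likelihood: direct
# numerical optimization over a softmax parameterization of the four gamete
# frequencies (no EM steps involved).  Used as an oracle for em_haplotypes.
oracle_max_loglik <- function(n) {
  n <- unclass(as.matrix(n))
  loglik <- function(f) {
    P <- matrix(c(f[1]^2, 2 * f[1] * f[2], f[2]^2,
                  2 * f[1] * f[3], 2 * f[1] * f[4] + 2 * f[2] * f[3],
                  2 * f[2] * f[4],
                  f[3]^2, 2 * f[3] * f[4], f[4]^2),
                3, 3, byrow = TRUE)
    use <- n > 0
    if (any(P[use] <= 0)) return(-Inf)
    sum(n[use] * log(P[use]))
  }
  obj <- function(th) {
    f <- exp(c(th, 0))
    -loglik(f / sum(f))
  }
  best <- stats::optim(c(0, 0, 0), obj, method = "BFGS",
                       control = list(maxit = 5000, reltol = 1e-15))
  f <- exp(c(best$par, 0))
  f <- f / sum(f)
  list(f = f, logL = -best$value)
}

# Random polymorphic genotype count table at one locus, for property tests.
random_locus_counts <- function(max_n = 60) {
  repeat {
    n <- sample(4:max_n, 1)
    p <- stats::runif(1, 0.1, 0.9)
    g <- sample(1:3, n, replace = TRUE, prob = c(p^2, 2 * p * (1 - p),
                                                 (1 - p)^2))
    tab <- tabulate(g, 3)
    if (tab[1] + tab[2] > 0 && tab[3] + tab[2] > 0)
      return(locus_counts(tab[1], tab[2], tab[3]))
  }
}
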