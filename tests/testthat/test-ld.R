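test_that("EM equals the closed-form gamete count estimate without double heterozygotes", {
  n <- matrix(c(30, 4, 1, 2, 0, 3, 1, 5, 20), 3, byrow = TRUE)
  est <- em_haplotypes(n)
  expect_identical(est$n_iter, 1L)
  expect_true(est$converged)
  # direct gamete counts / 2N
  k <- c(2 * 30 + 4 + 2, 4 + 2 * 1 + 3, 2 + 2 * 1 + 5, 3 + 5 + 2 * 20)
  expect_equal(unname(est$f), k / sum(k), tolerance = 1e-12)
})

test_that("EM resolves the single ambiguous individual in the MB table", {
  est <- em_haplotypes(survey_joint("MB"))
  expect_equal(unname(est$f), c(0.5515, 0.0258, 0.0619, 0.3608),
               tolerance = 2e-3)
  expect_gt(est$posterior_cis, 0.98)
  expect_equal(sum(est$f), 1, tolerance = 1e-9)
})

test_that("EM log-likelihood matches a direct numerical maximizer on small tables", {
  set.seed(5)
  for (i in 1:20) {
    repeat {
      n <- matrix(stats::rmultinom(1, sample(6:12, 1), rep(1, 9)), 3)
      mar <- c((2 * sum(n[1, ]) + sum(n[2, ])) / (2 * sum(n)),
               (2 * sum(n[, 1]) + sum(n[, 2])) / (2 * sum(n)))
      if (all(mar > 0 & mar < 1) && n[2, 2] < sum(n)) break
    }
    em <- em_haplotypes(n, tol = 1e-12, max_iter = 5000)
    oracle <- oracle_max_loglik(n)
    expect_equal(em$logL, oracle$logL, tolerance = 1e-6)
  }
})

test_that("an all-double-heterozygote sample is flagged non-identifiable", {
  n <- matrix(0, 3, 3)
  n[2, 2] <- 8
  est <- em_haplotypes(n)
  expect_true(est$non_identifiable)
})

test_that("LD statistics follow the standard D / D' / r2 definitions", {
  eq <- ld_statistics(c(0.35, 0.35, 0.15, 0.15))  # products of margins
  expect_equal(eq$D, 0, tolerance = 1e-12)
  expect_equal(eq$r2, 0, tolerance = 1e-12)
  full <- ld_statistics(c(0.5, 0, 0, 0.5))
  expect_equal(full$D, 0.25)
  expect_equal(full$D_prime, 1)
  expect_equal(full$r2, 1)
  expect_error(ld_statistics(c(0.6, 0.4, 0, 0)), "monomorphic")
  mb <- ld_statistics(em_haplotypes(survey_joint("MB")))
  expect_equal(round(mb$r2, 2), 0.67)
})

test_that("bootstrap SDs are seed-reproducible and shrink with sample size", {
  j <- survey_joint("MB")
  b1 <- bootstrap_haplotype_sd(j, B = 150, seed = 42)
  b2 <- bootstrap_haplotype_sd(j, B = 150, seed = 42)
  expect_identical(b1$sd, b2$sd)
  # quadrupling every cell should roughly halve the bootstrap SDs
  small <- matrix(c(30, 5, 2, 3, 4, 3, 2, 6, 25), 3, byrow = TRUE)
  big <- small * 4
  sd_small <- bootstrap_haplotype_sd(small, B = 200, seed = 1)$sd
  sd_big <- bootstrap_haplotype_sd(big, B = 200, seed = 1)$sd
  expect_true(all(sd_big < sd_small))
  expect_equal(mean(sd_small / sd_big), 2, tolerance = 0.35)
})

test_that("phase ambiguity inflates the bootstrap SD of f_MM", {
  # both tables have N = 40 and identical fitted gamete frequencies
  # (uniform 0.25), so the only difference is the phase ambiguity of the
  # double heterozygotes
  base <- matrix(c(8, 2, 8, 2, 0, 2, 8, 2, 8), 3, byrow = TRUE)
  with_het <- matrix(c(6, 2, 6, 2, 8, 2, 6, 2, 6), 3, byrow = TRUE)
  expect_equal(unname(em_haplotypes(with_het)$f), rep(0.25, 4),
               tolerance = 1e-9)
  sd_none <- bootstrap_haplotype_sd(base, B = 400, seed = 3)$sd[["MM"]]
  sd_het <- bootstrap_haplotype_sd(with_het, B = 400, seed = 3)$sd[["MM"]]
  expect_gt(sd_het, sd_none)
})

test_that("the LR permutation test detects the MB association", {
  res <- lr_test_association(survey_joint("MB"), n_perm = 10000, seed = 9)
  expect_lt(res$p_perm, 0.001)
  expect_gte(res$G, 0)
  expect_lt(res$p_chi2, 1e-10)
})

test_that("a perfectly associated table gives the entropy-gap G and minimal p", {
  n <- matrix(0, 3, 3)
  n[1, 1] <- 20
  n[3, 3] <- 20
  res <- lr_test_association(n, n_perm = 999, seed = 2)
  expect_equal(res$G, 4 * 40 * log(2), tolerance = 1e-9)
  expect_equal(res$p_perm, 1 / 1000)
})

test_that("monomorphic loci yield a null LR result", {
  n <- matrix(0, 3, 3)
  n[1, 1] <- 10
  n[1, 3] <- 10
  res <- lr_test_association(n, n_perm = 500, seed = 1)
  expect_true(is.na(res$p_perm))
  expect_identical(res$reason, "fixed")
})

test_that("phase-resolved Fisher test matches the resolved gamete table", {
  pk <- phase_known_exact_test(survey_joint("MB"))
  expect_identical(as.vector(pk$gamete_table), c(107, 12, 5, 70))
  expect_lt(pk$p_value, 1e-10)
  expect_equal(pk$p_value,
               stats::fisher.test(matrix(c(107, 12, 5, 70), 2))$p.value)
  # balanced gamete table, no double heterozygotes -> p = 1
  bal <- matrix(c(5, 0, 5, 0, 0, 0, 5, 0, 5), 3, byrow = TRUE)
  expect_equal(phase_known_exact_test(bal)$p_value, 1)
  # empty gamete margin is degenerate
  onlyM <- matrix(0, 3, 3)
  onlyM[1, 1] <- 5
  onlyM[1, 3] <- 5
  expect_error(phase_known_exact_test(onlyM), "margin")
})
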