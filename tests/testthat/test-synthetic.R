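test_that("identical seeds give bit-identical datasets", {
  p <- sim_params(n_individuals = 150, seed = 99)
  a <- simulate_population(p)
  b <- simulate_population(p)
  expect_identical(a, b)
  c <- simulate_population(sim_params(n_individuals = 150, seed = 100))
  expect_false(identical(a$records, c$records))
})

test_that("pure-pool and fully-mixed limits behave as expected", {
  # all-M pool: every diagnostic locus fixed MM, f undefined
  allm <- simulate_population(sim_params(n_individuals = 80, alpha = 1,
                                         cross_mating = 0, seed = 3))
  expect_true(all(allm$records$`SINE-X` == "MM"))
  lc <- tabulate_locus(allm$records, "SINE-X")
  expect_true(is.na(fis_weir_cockerham(lc)))
  # two pools, no interbreeding: no heterozygotes, f = 1, r2 = 1
  mix <- simulate_population(sim_params(n_individuals = 200, alpha = 0.5,
                                        cross_mating = 0, seed = 4))
  expect_false(any(mix$records$`SINE-X` == "MS"))
  expect_equal(fis_weir_cockerham(tabulate_locus(mix$records, "SINE-X")), 1)
  j <- tabulate_joint(mix$records, "SINE-X", "3L")
  expect_equal(ld_statistics(em_haplotypes(j))$r2, 1, tolerance = 1e-9)
})

test_that("full cross-mating restores panmixia", {
  set.seed(0)
  seeds <- sample.int(1e6, 100)
  fis <- vapply(seeds, function(s) {
    pop <- simulate_population(sim_params(n_individuals = 200, alpha = 0.5,
                                          cross_mating = 1, seed = s))
    as.numeric(fis_weir_cockerham(tabulate_locus(pop$records, "SINE-X")))
  }, numeric(1))
  se <- stats::sd(fis) / sqrt(length(fis))
  expect_lt(abs(mean(fis)), 3 * se + 1e-3)
})

test_that("Wahlund closed form gives the textbook values", {
  pp <- sim_params(pool_freq_M = 0.9, pool_freq_S = 0.1, alpha = 0.5,
                   cross_mating = 0)
  expect_equal(expected_wahlund_fis(pp, "SINE-X"), 0.64)
  same <- sim_params(pool_freq_M = 0.4, pool_freq_S = 0.4, cross_mating = 0)
  expect_equal(expected_wahlund_fis(same, "SINE-X"), 0)
  diag <- sim_params(pool_freq_M = 1, pool_freq_S = 0, alpha = 0.5,
                     cross_mating = 0)
  expect_equal(expected_wahlund_fis(diag, "SINE-X"), 1)
  expect_error(expected_wahlund_fis(sim_params(cross_mating = 0.5), "2L"),
               "cross_mating = 0")
})

test_that("simulated f brackets the Wahlund expectation", {
  pp <- sim_params(n_individuals = 500, pool_freq_M = 0.9,
                   pool_freq_S = 0.1, alpha = 0.5, cross_mating = 0)
  expected <- expected_wahlund_fis(pp, "SINE-X")
  set.seed(1)
  seeds <- sample.int(1e6, 200)
  fis <- vapply(seeds, function(s) {
    pp$seed <- s
    as.numeric(fis_weir_cockerham(
      tabulate_locus(simulate_population(pp)$records, "SINE-X")))
  }, numeric(1))
  se <- stats::sd(fis) / sqrt(length(fis))
  expect_lt(abs(mean(fis) - expected), 3 * se)
})

test_that("rDNA array simulation drives IGS calls through the thresholds", {
  a <- array_params()
  arr <- simulate_rdna_arrays(a, rep(c("MM", "MS", "SS"), each = 200),
                              seed = 8)
  th <- a$rflp_call_thresholds
  expect_identical(arr$igs_call,
                   ifelse(arr$pi <= th[1], "M",
                          ifelse(arr$pi >= th[2], "S", "MS")))
  # heterozygous ancestry centres pi near 0.5; parental classes near 0/1
  expect_lt(abs(stats::median(arr$pi[arr$sine_x == "MS"]) - 0.5), 0.1)
  expect_lt(stats::median(arr$pi[arr$sine_x == "MM"]), 0.2)
  expect_gt(stats::median(arr$pi[arr$sine_x == "SS"]), 0.8)
  # forced low pi with SS ancestry produces a type-2-like mismatch
  forced <- array_params(mixture = list(MM = c(2, 38), MS = c(20, 20),
                                        SS = c(2, 18)))
  arr2 <- simulate_rdna_arrays(forced, rep("SS", 300), seed = 9)
  cls <- mismatch_classify(arr2$igs_call[arr2$igs_call != "S"],
                           arr2$sine_x[arr2$igs_call != "S"])
  expect_true(any(cls == "hybrid_IGS_hom_SINE"))
})

test_that("mismatch frequency grows with array-mixture variance", {
  # same mean pi (0.05 / 0.5 / 0.95), increasing dispersion
  scale <- c(40, 8, 2)
  rates <- vapply(scale, function(s) {
    a <- array_params(mixture = list(MM = c(0.05, 0.95) * s,
                                     MS = c(0.5, 0.5) * s,
                                     SS = c(0.95, 0.05) * s))
    arr <- simulate_rdna_arrays(a, rep(c("MM", "MS", "SS"), each = 400),
                                seed = 17)
    igs3 <- c(M = "MM", MS = "MS", S = "SS")[arr$igs_call]
    mean(igs3 != arr$sine_x)
  }, numeric(1))
  expect_true(all(diff(rates) > 0))
})

test_that("noiseless traces recover pi exactly through the CNP pipeline", {
  a <- array_params(trace_noise_sd = 0)
  traces <- simulate_traces(c(0, 0.5, 1), a, seed = 5)
  scores <- vapply(traces, function(o) {
    s <- normalize_peak_heights(o)
    cnp_score(s[["s_M"]], s[["s_S"]])
  }, numeric(1))
  expect_equal(scores, c(0, 0.5, 1), tolerance = 1e-9)
})

test_that("the 2L null allele degrades calls as its frequency rises", {
  g <- rep(c("MM", "MS", "SS"), times = c(40, 20, 40))
  expect_identical(apply_null_allele(g, 0, seed = 2)$observed, g)
  expect_true(all(apply_null_allele(g, 1, seed = 2)$observed == "U"))
  nu <- 0.292
  big <- apply_null_allele(rep("MM", 5000), nu, seed = 6)
  frac <- mean(big$null_carrier == 2)
  se <- sqrt(nu^2 * (1 - nu^2) / 5000)
  expect_lt(abs(frac - nu^2), 3 * se)
  # null-carrying MM homozygotes surface as apparent heterozygotes
  expect_true(any(big$observed == "MS"))
  expect_true(any(big$observed == "U"))
})
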