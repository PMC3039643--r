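test_that("joint genotypes are classified into parental/F1/assorted classes", {
  res <- classify_joint_genotype(c("MM", "SS", "MS", "MM", "SS", NA),
                                 c("MM", "SS", "MS", "SS", "MS", "MM"))
  expect_identical(res$value[1:5],
                   c("parental_M", "parental_S", "f1_like", "assorted",
                     "assorted"))
  expect_identical(res$congruent[1:5], c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_true(is.na(res$value[6]))
  # congruent iff both loci share the genotype, for all 9 combinations
  g <- expand.grid(x = c("MM", "MS", "SS"), y = c("MM", "MS", "SS"),
                   stringsAsFactors = FALSE)
  cl <- classify_joint_genotype(g$x, g$y)
  expect_identical(cl$congruent, g$x == g$y)
})

test_that("IGS-vs-SINE mismatch taxonomy covers all call pairs", {
  expect_identical(mismatch_classify("M", "MS"), "pure_IGS_het_SINE")
  expect_identical(mismatch_classify("S", "MS"), "pure_IGS_het_SINE")
  expect_identical(mismatch_classify("MS", "SS"), "hybrid_IGS_hom_SINE")
  expect_identical(mismatch_classify("MS", "MM"), "hybrid_IGS_hom_SINE")
  expect_identical(mismatch_classify("M", "MM"), "concordant")
  expect_identical(mismatch_classify("MS", "MS"), "concordant")
  expect_identical(mismatch_classify("M", "SS"), "opposing_homozygote")
  expect_identical(mismatch_classify("S", "MM"), "opposing_homozygote")
  expect_error(mismatch_classify("X", "MM"), "igs")
})

test_that("chi-square wrapper matches the direct sum over random tables", {
  set.seed(21)
  for (i in 1:20) {
    repeat {
      dims <- sample(2:4, 2, replace = TRUE)
      tab <- matrix(stats::rpois(prod(dims), 8) + 1, dims[1], dims[2])
      if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) break
    }
    res <- contingency_chisq(tab, yates = "off")
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    expect_equal(res$chi2, sum((tab - E)^2 / E), tolerance = 1e-10)
    expect_equal(res$df, (dims[1] - 1L) * (dims[2] - 1L))
  }
})

test_that("Yates policy corrects 2x2 tables only", {
  t22 <- matrix(c(63, 45, 10, 131), 2)
  expect_true(contingency_chisq(t22)$yates)
  expect_equal(contingency_chisq(t22)$chi2, 75.04, tolerance = 0.01)
  expect_false(contingency_chisq(t22, yates = "off")$yates)
  t33 <- matrix(5:13, 3)
  expect_false(contingency_chisq(t33)$yates)
  expect_equal(contingency_chisq(matrix(c(10, 10, 10, 10), 2))$chi2, 0)
  expect_equal(contingency_chisq(matrix(c(10, 10, 10, 10), 2))$p, 1)
  expect_error(contingency_chisq(matrix(c(0, 0, 5, 5), 2, byrow = TRUE)),
               "zero margin")
})

test_that("class summary reproduces the published ratios and frequencies", {
  guinea <- survey_joint("Tot", "Guinea Bissau")
  gambia <- survey_joint("Tot", "The Gambia")
  s <- genotype_class_summary(list(`Guinea Bissau` = guinea,
                                   `The Gambia` = gambia),
                              drop_x_het = "The Gambia")
  per <- s$per_group
  gb <- per[per$group == "Guinea Bissau", ]
  gm <- per[per$group == "The Gambia", ]
  expect_equal(gb$parental, 0.336, tolerance = 5e-3)
  expect_equal(gb$congruent, 0.408, tolerance = 5e-3)
  expect_equal(gm$parental, 0.733, tolerance = 5e-3)
  expect_equal(gm$congruent, 0.740, tolerance = 5e-3)
  expect_equal(gb$m_ratio, 63 / 10)
  expect_equal(gb$s_ratio, 45 / 131)
  expect_identical(gb$m_ratio_label, "6.3 to 1 (63/10)")
  expect_identical(gb$s_ratio_label, "0.3 to 1 (45/131)")
  expect_equal(gm$m_ratio, 150 / 31)
  expect_equal(gm$s_ratio, 64 / 43)
  # the four association chi-squares behind the prose
  expect_equal(s$independence$`Guinea Bissau`$chi2, 48.6, tolerance = 0.1)
  expect_identical(s$independence$`Guinea Bissau`$df, 4L)
  expect_equal(s$independence$`The Gambia`$chi2, 179.4, tolerance = 0.1)
  expect_identical(s$independence$`The Gambia`$df, 2L)
  expect_equal(s$parental_vs_assorted$`Guinea Bissau`$chi2, 75.0,
               tolerance = 0.1)
  expect_equal(s$parental_vs_assorted$`The Gambia`$chi2, 17.5,
               tolerance = 0.1)
  expect_equal(s$congruent_by_group$chi2, 67.1, tolerance = 0.1)
})

test_that("class frequencies sum to 1 and degenerate groups yield null ratios", {
  one <- matrix(0, 3, 3)
  one[1, 1] <- 12
  s <- genotype_class_summary(list(only_parental_M = joint_counts(one)))
  per <- s$per_group
  expect_equal(per$parental_M + per$parental_S + per$f1_like + per$assorted,
               1)
  expect_equal(per$parental_M, 1)
  expect_true(is.na(per$m_ratio) && is.na(per$s_ratio))
  expect_null(s$independence$only_parental_M)
  expect_null(s$parental_vs_assorted$only_parental_M)
})
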