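test_that("alpha is 1 when all raters agree", {
  # distinct units, identical raters: perfect agreement, finite expectation
  m <- matrix(rep(c(1, 2, 3, 2), 3), ncol = 3)
  expect_equal(krippendorff_alpha(m), 1)
  # all values identical: zero expected disagreement, 1 by convention
  flat <- matrix(2, 4, 2)
  expect_warning(a <- krippendorff_alpha(flat), "convention")
  expect_equal(a, 1)
})

test_that("alpha matches the brute-force oracle on toy matrices", {
  m4 <- matrix(c(1, 2, 3, 3,
                 1, 2, 3, 2), ncol = 2)
  for (lvl in c("ordinal", "nominal", "interval")) {
    expect_equal(krippendorff_alpha(m4, lvl), bf_alpha(m4, lvl),
                 tolerance = 1e-10)
  }
  # with missing data and three raters
  m5 <- matrix(c(1, 2, 3, 3, 2,
                 1, 2, NA, 3, 2,
                 NA, 3, 3, 3, 1), ncol = 3)
  for (lvl in c("ordinal", "nominal", "interval")) {
    expect_equal(krippendorff_alpha(m5, lvl), bf_alpha(m5, lvl),
                 tolerance = 1e-10)
  }
})

test_that("alpha is invariant to unit permutation and drops when noise is injected", {
  set.seed(99)
  m <- matrix(sample(0:3, 24, replace = TRUE), ncol = 2)
  m[, 2] <- m[, 1]; m[1, 2] <- (m[1, 1] + 1) %% 4   # near-perfect
  a0 <- krippendorff_alpha(m)
  expect_equal(krippendorff_alpha(m[sample(nrow(m)), ]), a0,
               tolerance = 1e-12)
  m_noisy <- m
  m_noisy[2:4, 2] <- (m_noisy[2:4, 1] + 2) %% 4
  expect_lt(krippendorff_alpha(m_noisy), a0)
})

test_that("weighted kappa matches the defining po/pe formula", {
  a <- c(0, 0, 1, 1, 2, 2, 2, 1, 0, 2)
  b <- c(0, 1, 1, 1, 2, 0, 2, 1, 0, 2)
  for (w in c("linear", "quadratic")) {
    expect_equal(weighted_kappa(a, b, w), bf_weighted_kappa(a, b, w),
                 tolerance = 1e-10)
  }
  expect_equal(weighted_kappa(a, a), 1)
  # invariant under order/spacing-preserving relabeling
  expect_equal(weighted_kappa(a * 10 + 5, b * 10 + 5),
               weighted_kappa(a, b), tolerance = 1e-12)
})

test_that("ICC(A,1) matches the ANOVA mean-square oracle", {
  a <- c(9, 6, 8, 7, 10, 6)
  b <- c(2, 1, 4, 1, 5, 2)
  r <- icc_a1(a, b)
  expect_equal(r$icc, bf_icc_a1(a, b), tolerance = 1e-10)
  expect_lte(r$ci_low, r$icc)
  expect_gte(r$ci_high, r$icc)
  expect_equal(icc_a1(a, a)$icc, 1)
  # absolute agreement penalizes a constant offset
  off <- icc_a1(a, a + 3)
  expect_lt(off$icc, 1)
  expect_equal(stats::cor(a, a + 3), 1)
})

test_that("diagnostic concordance counts the confusion table directly", {
  ref <- c(rep("N+", 5), rep("N-", 5))
  prd <- c(rep("N+", 5), "N+", rep("N-", 4))
  r <- diagnostic_concordance(ref, prd)
  expect_equal(r$sensitivity, 100)
  expect_equal(r$specificity, 80)
  expect_equal(r$accuracy, 90)
  perf <- diagnostic_concordance(ref, ref)
  expect_equal(perf$accuracy, 100)
  allpos <- diagnostic_concordance(ref, rep("N+", 10))
  expect_equal(allpos$sensitivity, 100)
  expect_equal(allpos$specificity, 0)
  # AUC from perfectly separating scores
  r2 <- diagnostic_concordance(ref, prd, scores = c(10:6, 4, 5, 3, 2, 1))
  expect_equal(r2$auc, 1)
  onecls <- diagnostic_concordance(rep("N+", 4), c("N+", "N+", "N-", "N+"))
  expect_true(is.na(onecls$specificity))
})

test_that("score concordance bundles the published comparison metrics", {
  a <- c(3, 2, 2, 1, 0, 3, 2, 1)
  b <- c(3, 2, 1, 1, 0, 3, 3, 1)
  r <- score_concordance(a, b)
  expect_equal(r$exact_agreement, 100 * mean(a == b))
  expect_equal(r$within_one, 100)
  expect_equal(r$mean_abs_diff, mean(abs(a - b)))
  expect_equal(r$kendall_tau, bf_tau_b(a, b), tolerance = 1e-10)
  expect_equal(r$icc, bf_icc_a1(a, b), tolerance = 1e-10)
})

test_that("score file comparison joins on id and reports per column", {
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write.csv(data.frame(patient_id = c("a", "b", "c"),
                       LineB = c(9, 6, 3), LetC = c(40, 30, 10)), f1,
            row.names = FALSE)
  write.csv(data.frame(patient_id = c("c", "b", "a"),
                       LineB = c(3, 7, 9), LetC = c(10, 30, 40)), f2,
            row.names = FALSE)
  res <- compare_score_files(f1, f2)
  expect_named(res, c("LineB", "LetC"))
  expect_equal(res$LetC$exact_agreement, 100)
  expect_equal(res$LineB$exact_agreement, 100 * 2 / 3)
  unlink(c(f1, f2))
})
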