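test_that("Bland-Altman degenerate and four-point hand calculations", {
  # perfect agreement
  ba0 <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ba0$bias, 0)
  expect_equal(c(ba0$loa_low, ba0$loa_high), c(0, 0))

  # d = +10, -10, +10, -10 percent against a reference of 1
  ba <- bland_altman(c(1.1, 0.9, 1.1, 0.9), rep(1, 4))
  sd_hand <- sqrt(sum((c(10, -10, 10, -10))^2) / 3)   # 11.547
  expect_equal(ba$bias, 0)
  expect_equal(ba$sd_d, sd_hand)
  expect_equal(ba$loa_high, 1.96 * sd_hand)           # 22.63
  expect_equal(ba$loa_low, -1.96 * sd_hand)
  expect_equal(ba$ci_bias, c(-1, 1) * 1.96 * sd_hand / 2)
  expect_equal(ba$ci_loa_high,
               1.96 * sd_hand + c(-1, 1) * 1.96 * sqrt(3 / 4) * sd_hand)
  # invariants: LoA bracket the bias, intervals contain their estimates
  expect_true(ba$loa_low <= ba$bias && ba$bias <= ba$loa_high)
  expect_true(ba$ci_bias[1] <= ba$bias && ba$bias <= ba$ci_bias[2])
})

test_that("pair-swapped mirror negates the bias in pair-mean mode", {
  set.seed(71)
  a <- rlnorm(100, 0, 0.3); b <- rlnorm(100, 0, 0.3)
  f <- bland_altman(a, b, "pair_mean")
  g <- bland_altman(b, a, "pair_mean")
  expect_equal(f$bias, -g$bias)
  expect_equal(f$loa_high, -g$loa_low)
})

test_that("Bland-Altman input validation", {
  expect_error(bland_altman(1, 1), "2 pairs")
  expect_error(bland_altman(c(1, -1), c(1, 1)), "positive")
  expect_error(bland_altman(c(1, 2, 3), c(1, 2)), "lengths")
})

test_that("zero-noise matched-form pipeline has exactly zero bias", {
  coh <- generate_cohort(zero_noise_config(n = 100, seed = 73))
  cc <- correct_cohort(coh, correction_model(
    factors = c(all = 0.037, healthy = 0.037, bmi_gt_35 = 0.037)))
  ba <- bland_altman(cc$tg_corrected, coh$v2_tg)
  expect_equal(ba$bias, 0, tolerance = 1e-10)
  expect_equal(ba$sd_d, 0, tolerance = 1e-10)
})

test_that("duplicate CV matches single-pair hand arithmetic", {
  expect_equal(duplicate_cv(1.0, 1.0)$cv_tb_mean, 0)
  r <- duplicate_cv(1.0, 1.2)
  expect_equal(r$cv_tb_mean, 100 * (0.2 / sqrt(2)) / 1.1)   # 12.86%
  expect_equal(r$n, 1)
})

test_that("CV decomposition identity with truncation at zero", {
  # the published identity: cv_tb 17.1%, cv_anal 1.5% -> cv_biol 17.03%
  expect_equal(sqrt(17.1^2 - 1.5^2), 17.03408, tolerance = 1e-6)
  set.seed(75)
  x1 <- rlnorm(200, 0, 0.2); x2 <- rlnorm(200, 0, 0.2)
  r0 <- duplicate_cv(x1, x2, cv_anal = 0)
  expect_equal(r0$cv_biol, r0$cv_tb_mean)            # no analytical share
  r1 <- duplicate_cv(x1, x2, cv_anal = 1.5)
  expect_equal(r1$cv_biol, sqrt(r1$cv_tb_mean^2 - 1.5^2))
  rbig <- duplicate_cv(x1, x2, cv_anal = 500)        # analytical dominates
  expect_equal(rbig$cv_biol, 0)
  expect_error(duplicate_cv(1, c(1, 2)), "lengths")
})

test_that("simulated cohort reproduces the configured duplicate-based CV", {
  cfg <- quick_config(n = 10000, seed = 77)
  coh <- generate_cohort(cfg)
  cc <- correct_cohort(coh, correction_model(
    factors = c(all = 0.037, healthy = 0.037, bmi_gt_35 = 0.037)))
  r <- duplicate_cv(cc$tg_corrected, coh$v2_tg, cv_anal = cfg$cv_anal)
  target <- sqrt(cfg$cv_biol^2 + cfg$cv_anal^2)      # ~17.07
  expect_lt(abs(r$cv_tb_mean - target), 1.0)
})

test_that("quantile summary uses order-statistic interpolation", {
  expect_equal(quantile_summary(1:5),
               c(mean = 3, median = 3, q25 = 2, q75 = 4))
  expect_equal(unname(quantile_summary(7)), rep(7, 4))
  set.seed(79)
  v <- rnorm(37)
  expect_equal(quantile_summary(v), quantile_summary(sample(v)))
  expect_error(quantile_summary(NA_real_), "at least one")
})

test_that("signed-rank p-values agree with exhaustive enumeration", {
  set.seed(1)
  for (i in 1:40) {
    d <- round(rnorm(sample(8:10, 1), mean = 0.3), 3)
    d <- d[d != 0]
    approx_p <- wilcoxon_signed_rank(d)$p_value
    exact_p <- wilcoxon_exact_enum(d)
    expect_lt(abs(approx_p - exact_p), 0.02)
  }
})

test_that("signed-rank degenerate and symmetric cases", {
  expect_warning(out <- wilcoxon_signed_rank(rep(1, 5), rep(1, 5)),
                 "all paired differences are zero")
  expect_equal(out$p_value, 1)
  # antisymmetric differences put the statistic at its null mean n(n+1)/4
  d <- c(1, -1, 2, -2, 3, -3)
  r <- wilcoxon_signed_rank(d)
  expect_equal(r$statistic, length(d) * (length(d) + 1) / 4)
  # zero differences are dropped before ranking
  expect_equal(wilcoxon_signed_rank(c(d, 0, 0))$statistic, r$statistic)
})

test_that("chi-square prevalence comparison matches the Pearson formula", {
  r0 <- chi2_prevalence(10, 100, 10, 100)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  # hand-computed: n(ad-bc)^2 / (row1 row2 col1 col2)
  r <- chi2_prevalence(30, 100, 10, 100)
  expect_equal(r$statistic,
               200 * (30 * 90 - 70 * 10)^2 / (100 * 100 * 40 * 160))  # 12.5
  # symmetric in the two groups
  r_swap <- chi2_prevalence(10, 100, 30, 100)
  expect_equal(r$statistic, r_swap$statistic)
  expect_equal(r$p_value, r_swap$p_value)
  expect_error(chi2_prevalence(0, 100, 0, 100), "margin")
  expect_error(chi2_prevalence(10, 0, 1, 10), "positive")
})

test_that("McNemar variant counts discordant pairs", {
  s1 <- c(TRUE, TRUE, FALSE, FALSE, TRUE, NA)
  s2 <- c(TRUE, FALSE, TRUE, FALSE, FALSE, TRUE)
  r <- mcnemar_prevalence(s1, s2)
  expect_equal(r$b, 2)      # s1-only positives among complete pairs
  expect_equal(r$c, 1)
  expect_warning(r0 <- mcnemar_prevalence(c(TRUE, FALSE), c(TRUE, FALSE)),
                 "discordant")
  expect_equal(r0$p_value, 1)
})

test_that("misclassification report: absolute and signed percentage points", {
  r <- misclassification_report(56.4, 51.3)
  expect_equal(r$diff_pp, 5.1)
  expect_equal(r$signed_pp, -5.1)
  r2 <- misclassification_report(35.5, 37.6)
  expect_equal(r2$diff_pp, 2.1)
  expect_equal(r2$signed_pp, 2.1)
  expect_equal(misclassification_report(40, 40)$diff_pp, 0)
  expect_error(misclassification_report(-1, 50), "0, 100")
  expect_error(misclassification_report(50, 101), "0, 100")
})
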