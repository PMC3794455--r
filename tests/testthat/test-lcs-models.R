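test_that("the paired t-test reproduces the closed-form oracle on the toy", {
  tt <- paired_t_test(toy_df())
  expect_equal(tt$d, 2)
  expect_equal(tt$se_d, sqrt((2 / 3) / 4), tolerance = 1e-12)
  expect_equal(tt$statistic, 2 / sqrt((2 / 3) / 4), tolerance = 1e-12)
  expect_equal(tt$df, 3)
  o <- oracle_ttest(toy_df()$y1, toy_df()$y2)
  expect_equal(tt$p.value, o$p, tolerance = 1e-12)
  expect_equal(tt$rho, 8 / sqrt(65), tolerance = 1e-12)
  # cross-check against the reference implementation
  ref <- t.test(toy_df()$y2, toy_df()$y1, paired = TRUE)
  expect_equal(tt$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(tt$p.value, ref$p.value, tolerance = 1e-12)
})

test_that("a null sample gives t = 0, p = 1 and uniform change is rejected as degenerate", {
  x <- data.frame(y1 = c(1, 2, 3, 4), y2 = c(4, 3, 2, 1))  # mean2 == mean1
  tt <- paired_t_test(x)
  expect_equal(tt$statistic, 0)
  expect_equal(tt$p.value, 1)
  stable <- data.frame(y1 = c(1, 2, 3), y2 = c(3, 4, 5))  # y2 = y1 + 2
  expect_error(paired_t_test(stable), "Degenerate change")
})

test_that("the correlated LCS fit is the paired t-test with a normal reference", {
  fit <- fit_lcs_correlated(toy_df())
  expect_equal(unname(fit$estimates["mu_delta"]), 2, tolerance = 1e-8)
  expect_equal(unname(fit$se["mu_delta"]), sqrt((2 / 3) / 4), tolerance = 1e-8)
  expect_equal(unname(fit$crit_ratio["mu_delta"]), 4.898979, tolerance = 1e-5)
  expect_equal(unname(fit$p_value["mu_delta"]),
               2 * pnorm(-2 / sqrt((2 / 3) / 4)), tolerance = 1e-8)
  # fixing the level-change covariance to zero leaves d and SE unchanged
  fit0 <- fit_lcs_correlated(toy_df(), cov_fixed_zero = TRUE)
  expect_equal(fit0$df, 1)
  expect_equal(unname(fit0$estimates["mu_delta"]),
               unname(fit$estimates["mu_delta"]), tolerance = 1e-8)
  expect_equal(unname(fit0$se["mu_delta"]), unname(fit$se["mu_delta"]),
               tolerance = 1e-7)
})

test_that("the self-feedback fit matches the regression-of-change oracle", {
  fit <- fit_lcs_sfm(toy_df())
  expect_equal(unname(fit$estimates["gamma"]), 0.6, tolerance = 1e-8)
  expect_equal(unname(fit$estimates["alpha"]), 2, tolerance = 1e-8)
  expect_equal(unname(fit$estimates["psi"]), (2 / 3) * 0.1, tolerance = 1e-8)
  expect_equal(unname(fit$se["alpha"]), sqrt((2 / 3) * 0.1 / 4),
               tolerance = 1e-6)
  expect_equal(unname(fit$crit_ratio["alpha"]), 15.49193, tolerance = 1e-4)
  o <- oracle_sfm(toy_df()$y1, toy_df()$y2)
  expect_equal(unname(fit$estimates["gamma"]), o$gamma, tolerance = 1e-8)
  expect_equal(unname(fit$p_value["alpha"]), o$p, tolerance = 1e-6)
})

test_that("uncorrelated baseline and change removes the conditioning gain", {
  # sd1 = 1, sd2 = 2, rho = 0.5 makes cov(Y1, D) = 0 exactly
  x <- paired_from_moments(60, 0, 1, -0.4, 2, rho = 0.5, seed = 5)
  sfm <- fit_lcs_sfm(x)
  corr <- fit_lcs_correlated(x)
  expect_equal(unname(sfm$estimates["gamma"]), 0, tolerance = 1e-7)
  expect_equal(unname(sfm$se["alpha"]), unname(corr$se["mu_delta"]),
               tolerance = 1e-6)
})

test_that("the lagged model recovers beta = 1 + gamma and stability identities", {
  ar <- fit_ar_lagged(toy_df())
  expect_equal(unname(ar$estimates["beta"]), 1.6, tolerance = 1e-8)
  sfm <- fit_lcs_sfm(toy_df())
  expect_equal(unname(ar$estimates["beta"]),
               1 + unname(sfm$estimates["gamma"]), tolerance = 1e-8)
  # near-perfect stability: y2 = y1 + c + tiny noise pushes beta to 1, gamma to 0
  set.seed(17)
  y1 <- rnorm(50)
  x <- data.frame(y1 = y1, y2 = y1 + 2 + rnorm(50, sd = 1e-4))
  expect_equal(unname(fit_ar_lagged(x)$estimates["beta"]), 1, tolerance = 1e-3)
  expect_equal(unname(fit_lcs_sfm(x)$estimates["gamma"]), 0, tolerance = 1e-3)
  # equal wave variances: |gamma| is the complement of the standardized stability
  xeq <- paired_from_moments(80, 0, 1, -0.3, 1, rho = 0.6, seed = 9)
  areq <- fit_ar_lagged(xeq)
  gameq <- unname(fit_lcs_sfm(xeq)$estimates["gamma"])
  expect_equal(abs(gameq), 1 - areq$standardized_stability, tolerance = 1e-8)
})

test_that("exactly collinear waves raise a singular-data error", {
  stable <- data.frame(y1 = c(1, 2, 3, 4), y2 = c(3, 4, 5, 6))
  expect_error(fit_ar_lagged(stable), "collinear|converge")
})

test_that("the self-feedback SE never exceeds the correlated SE", {
  set.seed(41)
  for (i in 1:15) {
    x <- rbvn(sample(6:200, 1), mu2 = rnorm(1), s1 = runif(1, 0.5, 2),
              s2 = runif(1, 0.5, 2), rho = runif(1, -0.8, 0.8))
    se_sfm <- unname(fit_lcs_sfm(x)$se["alpha"])
    se_cor <- unname(fit_lcs_correlated(x)$se["mu_delta"])
    expect_lte(se_sfm, se_cor * (1 + 1e-6))
  }
})

test_that("fitting the self-feedback model without centering warns", {
  x <- rbvn(30, mu1 = 5, mu2 = 4.5, rho = 0.5)
  expect_warning(fit_lcs_sfm(x, center = FALSE), "not centered")
  expect_silent(suppressWarnings(fit_lcs_sfm(x)))
})

test_that("tidiers and glance return well-formed tibbles", {
  fit <- fit_lcs_sfm(toy_df())
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("term", "estimate", "std.error", "statistic", "p.value"))
  expect_equal(nrow(td), 5)
  gl <- glance(fit)
  expect_equal(gl$df, 0)
  expect_true(gl$converged)
  expect_s3_class(autoplot(fit), "ggplot")
})
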