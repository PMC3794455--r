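test_that("the ML discrepancy matches direct evaluation of the fit function", {
  # S = I, Sigma = diag(1, 2), equal means: F = ln 2 + 1.5 - 2
  m <- moments_from_summary(10, 0, 1, 0, 1, rho = 0)
  f <- ml_discrepancy(m, mu = c(0, 0), sigma = diag(c(1, 2)))
  expect_equal(f, log(2) - 0.5, tolerance = 1e-12)
  # perfect fit
  expect_equal(ml_discrepancy(m, c(0, 0), diag(2)), 0, tolerance = 1e-12)
  # F >= 0 and zero only at the sample moments
  set.seed(3)
  for (i in 1:25) {
    mu <- rnorm(2)
    a <- rnorm(2)
    sigma <- crossprod(matrix(rnorm(4), 2)) + diag(0.1, 2)
    expect_gte(ml_discrepancy(m, mu, sigma), 0)
  }
  expect_error(ml_discrepancy(m, c(0, 0), matrix(c(1, 1, 1, 1), 2)),
               "singular")
})

test_that("implied moments follow the structural equations", {
  # correlated specification: direct substitution
  im <- implied_moments(
    spec_lcs_correlated(),
    c(mu1 = 0, mu_delta = -0.395, var1 = 1, var_delta = 1, cov1_delta = 0)
  )
  expect_equal(im$mu, c(0, -0.395))
  expect_equal(im$sigma, matrix(c(1, 1, 1, 2), 2))
  # self-feedback: Cov(Y1, Y2) = (1 + gamma) var1
  im2 <- implied_moments(
    spec_lcs_sfm(),
    c(mu1 = 0, var1 = 5 / 3, alpha = 2, gamma = 0.6, psi = 0.05)
  )
  expect_equal(im2$sigma[1, 2], (1 + 0.6) * 5 / 3)
  expect_equal(im2$sigma[2, 2], 1.6^2 * 5 / 3 + 0.05)
  expect_equal(im2$mu[2], 2)
  expect_error(implied_moments(spec_lcs_sfm(), c(mu1 = 0)), "free parameter")
})

test_that("saturated fits reproduce sample moments with zero discrepancy", {
  set.seed(11)
  specs <- list(spec_lcs_correlated(), spec_lcs_sfm(), spec_ar_lagged())
  for (i in 1:8) {
    x <- rbvn(sample(6:120, 1), mu2 = rnorm(1), rho = runif(1, -0.8, 0.8))
    m <- compute_moments(x)
    sm <- matrix(c(m$var1, m$cov12, m$cov12, m$var2), 2)
    for (spec in specs) {
      fit <- fit_path_model(spec, m)
      expect_equal(fit$df, 0)
      expect_lt(fit$f_min, 1e-10)
      im <- implied_moments(spec, fit$estimates)
      expect_equal(im$mu, c(m$mean1, m$mean2), tolerance = 1e-6)
      expect_equal(im$sigma, sm, tolerance = 1e-6)
      expect_true(all(is.finite(fit$se)) && all(fit$se > 0))
      # critical ratio is estimate / SE by construction
      expect_equal(fit$crit_ratio, fit$estimates / fit$se, tolerance = 1e-10)
    }
  }
})

test_that("the constrained-model chi-square equals the closed-form likelihood ratio", {
  set.seed(23)
  for (i in 1:30) {
    x <- rbvn(sample(5:300, 1), mu2 = rnorm(1, -0.3), s1 = runif(1, 0.5, 2),
              s2 = runif(1, 0.5, 2), rho = runif(1, -0.85, 0.85))
    fit <- fit_path_model(spec_lcs_no_sfm(), compute_moments(x))
    expect_equal(fit$df, 1)
    expect_equal(fit$chi_square, oracle_gamma0_chisq(x$y1, x$y2),
                 tolerance = 1e-6)
  }
})

test_that("chi-square scale and denominator flags change only what they should", {
  x <- rbvn(40, mu2 = -0.5, rho = 0.5)
  m1 <- compute_moments(x)
  fit_nm1 <- fit_path_model(spec_lcs_no_sfm(), m1, chisq_scale = "n-1")
  fit_n <- fit_path_model(spec_lcs_no_sfm(), m1, chisq_scale = "n")
  expect_equal(fit_n$chi_square / fit_nm1$chi_square, 40 / 39,
               tolerance = 1e-8)
  expect_equal(fit_n$f_min, fit_nm1$f_min, tolerance = 1e-10)
})

test_that("self-feedback and lagged autoregressive fits are the same model", {
  set.seed(31)
  for (i in 1:10) {
    x <- rbvn(sample(8:150, 1), mu2 = rnorm(1), rho = runif(1, -0.8, 0.8))
    m <- compute_moments(center_on_wave1(x))
    sfm <- fit_path_model(spec_lcs_sfm(), m)
    ar <- fit_path_model(spec_ar_lagged(), m)
    expect_equal(sfm$f_min, ar$f_min, tolerance = 1e-10)
    expect_equal(sfm$chi_square, ar$chi_square, tolerance = 1e-8)
    expect_equal(unname(ar$estimates["beta"]),
                 1 + unname(sfm$estimates["gamma"]), tolerance = 1e-8)
    expect_equal(unname(ar$estimates["psi"]), unname(sfm$estimates["psi"]),
                 tolerance = 1e-8)
  }
})

test_that("a model spec cannot exceed the saturated parameter count", {
  expect_error(
    model_spec("too big", free = letters[1:6], implied = identity,
               start = identity),
    "At most 5"
  )
})
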