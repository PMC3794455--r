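#' Model specifications for the two-wave latent change score family
#'
#' Builders for the four concrete models: the correlated level–change
#' specification (the SEM form of the paired t-test), the self-feedback
#' specification in which baseline predicts change, its gamma = 0 constrained
#' version, and the lagged autoregressive model `Y2 = c + beta * Y1 + e`
#' (the same model as the self-feedback form in different coordinates, with
#' `beta = 1 + gamma`).
#'
#' All four write the follow-up as `Y2 = Y1 + LCS` with unit loadings, zero
#' Y2 intercept and zero Y2 residual, so the latent variable is the exact
#' change score. They differ only in how the change relates to the baseline:
#' via a free covariance (`spec_lcs_correlated`), a directed path
#' (`spec_lcs_sfm`), or neither (`cov_fixed_zero = TRUE`, `spec_lcs_no_sfm`).
#'
#' @param cov_fixed_zero Fix the level–change covariance to zero (df = 1)
#'   instead of estimating it (saturated, df = 0).
#' @return A [model_spec()].
#' @name lcs_specs
NULL

#' @rdname lcs_specs
#' @export
spec_lcs_correlated <- function(cov_fixed_zero = FALSE) {
  free <- c("mu1", "mu_delta", "var1", "var_delta",
            if (!cov_fixed_zero) "cov1_delta")
  fixed <- if (cov_fixed_zero) list(cov1_delta = 0) else list()
  model_spec(
    name = if (cov_fixed_zero) "LCS (level-change covariance fixed to 0)"
           else "LCS (level and change correlated)",
    free = free, fixed = fixed,
    implied = function(th) {
      list(
        mu = c(th$mu1, th$mu1 + th$mu_delta),
        sigma = matrix(c(
          th$var1, th$var1 + th$cov1_delta,
          th$var1 + th$cov1_delta,
          th$var1 + th$var_delta + 2 * th$cov1_delta), 2, 2)
      )
    },
    start = function(m) {
      d <- moment_derived(m)
      c(mu1 = m$mean1, mu_delta = d$d_bar, var1 = m$var1,
        var_delta = d$var_d, cov1_delta = d$cov_y1_d)
    },
    positive = c("var1", "var_delta")
  )
}

#' @rdname lcs_specs
#' @export
spec_lcs_sfm <- function() {
  model_spec(
    name = "LCS with self-feedback path",
    free = c("mu1", "var1", "alpha", "gamma", "psi"),
    implied = function(th) {
      b <- 1 + th$gamma
      list(
        mu = c(th$mu1, th$alpha + b * th$mu1),
        sigma = matrix(c(th$var1, b * th$var1,
                         b * th$var1, b^2 * th$var1 + th$psi), 2, 2)
      )
    },
    start = function(m) {
      d <- moment_derived(m)
      g <- d$cov_y1_d / m$var1
      c(mu1 = m$mean1, var1 = m$var1,
        alpha = d$d_bar - g * m$mean1, gamma = g,
        psi = max(d$var_d * (1 - d$r_y1_d^2), 1e-10))
    },
    positive = c("var1", "psi")
  )
}

#' @rdname lcs_specs
#' @export
spec_lcs_no_sfm <- function() {
  sfm <- spec_lcs_sfm()
  model_spec(
    name = "LCS with self-feedback fixed to 0",
    free = setdiff(sfm$free, "gamma"),
    fixed = list(gamma = 0),
    implied = sfm$implied,
    start = function(m) {
      d <- moment_derived(m)
      c(mu1 = m$mean1, var1 = m$var1, alpha = d$d_bar, psi = d$var_d)
    },
    positive = c("var1", "psi")
  )
}

#' @rdname lcs_specs
#' @export
spec_ar_lagged <- function() {
  model_spec(
    name = "Lagged autoregressive (Y1 -> Y2)",
    free = c("mu1", "var1", "intercept", "beta", "psi"),
    implied = function(th) {
      list(
        mu = c(th$mu1, th$intercept + th$beta * th$mu1),
        sigma = matrix(c(th$var1, th$beta * th$var1,
                         th$beta * th$var1,
                         th$beta^2 * th$var1 + th$psi), 2, 2)
      )
    },
    start = function(m) {
      b <- m$cov12 / m$var1
      c(mu1 = m$mean1, var1 = m$var1,
        intercept = m$mean2 - b * m$mean1, beta = b,
        psi = max(m$var2 - b^2 * m$var1, 1e-10))
    },
    positive = c("var1", "psi")
  )
}

#' Classical paired t-test
#'
#' Tests whether the mean within-subject difference is zero, with
#' `SE = s_D / sqrt(n)` (unbiased difference-score variance) and the t
#' reference distribution with n - 1 degrees of freedom.
#'
#' @param x A data frame of paired measurements (columns `y1`, `y2`) or a
#'   `moment_summary`.
#' @param y1,y2 Column names when `x` is a data frame.
#' @param denominator Moment denominator convention used when `x` is a data
#'   frame; the test statistic itself always uses the unbiased difference
#'   variance.
#'
#' @return An `lcs_ttest` object with `d` (mean difference), `se_d`,
#'   `statistic` (t), `df`, `p.value` (two-sided t), `rho` (paired
#'   correlation) and `n`. Methods: [tidy()], [glance()], `print()`.
#' @export
#' @examples
#' paired_t_test(data.frame(y1 = c(1, 2, 3, 4), y2 = c(2, 4, 5, 7)))
paired_t_test <- function(x, y1 = "y1", y2 = "y2",
                          denominator = c("n-1", "n")) {
  denominator <- match.arg(denominator)
  m <- as_moments(x, denominator = denominator, y1 = y1, y2 = y2)
  der <- moment_derived(m)
  v_d <- var_d_unbiased(m)
  if (v_d <= 0) {
    abort("Degenerate change: the difference score has zero variance (uniform change across subjects).")
  }
  d <- der$d_bar
  se <- sqrt(v_d / m$n)
  t_stat <- d / se
  structure(
    list(d = d, se_d = se, statistic = t_stat, df = m$n - 1L,
         p.value = p_t_two_sided(t_stat, m$n - 1L),
         rho = der$rho, n = m$n),
    class = "lcs_ttest"
  )
}

#' @export
print.lcs_ttest <- function(x, ...) {
  cat("Paired t-test\n")
  cat(sprintf("  d = %.4f, SE = %.4f, t(%d) = %.4f, p = %.4g\n",
              x$d, x$se_d, x$df, x$statistic, x$p.value))
  cat(sprintf("  paired correlation rho = %.4f  (n = %d)\n", x$rho, x$n))
  invisible(x)
}

#' @describeIn paired_t_test One-row tibble with `estimate`, `std.error`,
#'   `statistic`, `df`, `p.value`, `rho`, `n`.
#' @param ... Unused.
#' @export
tidy.lcs_ttest <- function(x, ...) {
  tibble::tibble(
    term = "mean change", estimate = x$d, std.error = x$se_d,
    statistic = x$statistic, df = x$df, p.value = x$p.value,
    rho = x$rho, n = x$n
  )
}

#' @describeIn paired_t_test Alias of the tidier (the test is its own
#'   one-row summary).
#' @export
glance.lcs_ttest <- function(x, ...) tidy(x)

# Shared front end of the fit_lcs_* functions: moments + optional centering.
prepare_moments <- function(x, center, denominator, y1, y2) {
  m <- as_moments(x, denominator = denominator, y1 = y1, y2 = y2)
  if (center) m <- center_moments(m)
  m
}

#' Fit the latent change score models
#'
#' `fit_lcs_correlated()` fits the SEM form of the paired t-test: baseline
#' level and latent change are allowed to covary (saturated, df = 0). Its mean
#' change equals the classical `d` and its SE equals the classical paired-test
#' SE; only the reference distribution differs (standard normal for the
#' critical ratio rather than t with n - 1 df).
#'
#' `fit_lcs_sfm()` replaces the covariance with a directed self-feedback path
#' `gamma` from baseline to change (also saturated). With centering on the
#' wave-1 mean (the default) the intercept `alpha` is the mean change at the
#' average baseline, and its SE shrinks by `sqrt(1 - r^2)` relative to the
#' correlated form, where `r` is the baseline–difference correlation.
#'
#' `fit_lcs_no_sfm()` fixes `gamma = 0` (df = 1); its chi-square is the
#' likelihood-ratio test of the no-self-feedback constraint and equals
#' `-(n-1) log(1 - r^2)` under the default scale.
#'
#' `fit_ar_lagged()` fits `Y2 = c + beta * Y1 + e`; `beta = 1 + gamma`
#' exactly, and the standardized stability `beta * sd1/sd2` is attached as
#' `$standardized_stability`.
#'
#' @inheritParams paired_t_test
#' @param center Center both waves on the wave-1 mean before fitting
#'   (default `TRUE`; recommended so the mean-change parameters are
#'   interpretable).
#' @param cov_fixed_zero For the correlated specification, fix the
#'   level–change covariance to zero (df = 1). The mean change and its SE are
#'   unaffected.
#' @param chisq_scale Chi-square convention, see [fit_path_model()].
#'
#' @return An `lcs_fit` (see [fit_path_model()]).
#' @export
#' @examples
#' toy <- data.frame(y1 = c(1, 2, 3, 4), y2 = c(2, 4, 5, 7))
#' fit_lcs_correlated(toy)
#' fit_lcs_sfm(toy)
fit_lcs_correlated <- function(x, cov_fixed_zero = FALSE, center = TRUE,
                               y1 = "y1", y2 = "y2",
                               denominator = c("n-1", "n"),
                               chisq_scale = c("n-1", "n")) {
  denominator <- match.arg(denominator)
  m <- prepare_moments(x, center, denominator, y1, y2)
  fit_path_model(spec_lcs_correlated(cov_fixed_zero), m,
                 chisq_scale = match.arg(chisq_scale))
}

#' @rdname fit_lcs_correlated
#' @export
fit_lcs_sfm <- function(x, center = TRUE, y1 = "y1", y2 = "y2",
                        denominator = c("n-1", "n"),
                        chisq_scale = c("n-1", "n")) {
  denominator <- match.arg(denominator)
  m <- prepare_moments(x, center, denominator, y1, y2)
  if (!center && abs(m$mean1) > 1e-8) {
    warn(paste("Baseline is not centered: the self-feedback intercept is the",
               "expected change at baseline 0, not at the average baseline."))
  }
  fit_path_model(spec_lcs_sfm(), m, chisq_scale = match.arg(chisq_scale))
}

#' @rdname fit_lcs_correlated
#' @export
fit_lcs_no_sfm <- function(x, center = TRUE, y1 = "y1", y2 = "y2",
                           denominator = c("n-1", "n"),
                           chisq_scale = c("n-1", "n")) {
  denominator <- match.arg(denominator)
  m <- prepare_moments(x, center, denominator, y1, y2)
  fit_path_model(spec_lcs_no_sfm(), m, chisq_scale = match.arg(chisq_scale))
}

#' @rdname fit_lcs_correlated
#' @export
fit_ar_lagged <- function(x, center = TRUE, y1 = "y1", y2 = "y2",
                          denominator = c("n-1", "n"),
                          chisq_scale = c("n-1", "n")) {
  denominator <- match.arg(denominator)
  m <- prepare_moments(x, center, denominator, y1, y2)
  fit <- fit_path_model(spec_ar_lagged(), m, chisq_scale = match.arg(chisq_scale))
  fit$standardized_stability <-
    unname(fit$estimates["beta"]) * sqrt(m$var1 / m$var2)
  fit
}

# ---------------------------------------------------------------------------
# Closed-form ML estimators. These are the analytic solutions of the same
# likelihoods the engine maximizes (asserted equal in the test suite); the
# Monte-Carlo harness uses them so large replication studies stay fast.

# Correlated specification: mean change, SE, CR, normal p.
correlated_stats <- function(m) {
  d <- moment_derived(m)
  se <- sqrt(var_d_unbiased(m) / m$n)
  cr <- (d$d_bar) / se
  list(estimate = d$d_bar, se = se, cr = cr, p = 2 * pnorm(-abs(cr)))
}

# Self-feedback specification on centered moments: gamma, alpha, SE(alpha),
# CR, normal p. psi uses the var_D * (1 - r^2) form under the n-1 convention.
sfm_stats <- function(m) {
  mc <- center_moments(m)
  d <- moment_derived(mc)
  gamma <- d$cov_y1_d / mc$var1
  v_d <- var_d_unbiased(mc)
  psi <- v_d * (1 - d$r_y1_d^2)
  if (psi <= 0) abort("Degenerate data: change is an exact function of baseline.")
  se <- sqrt(psi / mc$n)
  cr <- d$d_bar / se
  list(gamma = gamma, alpha = d$d_bar, psi = psi, se = se, cr = cr,
       p = 2 * pnorm(-abs(cr)))
}

# Likelihood-ratio chi-square of the gamma = 0 constraint.
gamma0_chisq <- function(m, chisq_scale = "n-1") {
  d <- moment_derived(m)
  scale_factor <- if (chisq_scale == "n-1") m$n - 1 else m$n
  -scale_factor * log(1 - d$r_y1_d^2)
}
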