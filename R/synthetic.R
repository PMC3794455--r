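#' Simulation design for bivariate-normal paired data
#'
#' Describes the population from which paired two-wave samples are drawn:
#' means, SDs and correlation of (Y1, Y2), the sample size, the number of
#' Monte-Carlo replications, the master seed, and the nominal test level.
#' The defaults mirror a glycated-haemoglobin-style regime: two positively
#' correlated continuous waves (SD about 1.3, correlation about 0.57) with a
#' small negative mean change.
#'
#' @param n Sample size per replication (>= 3).
#' @param mu1,mu2 True wave means.
#' @param sigma1,sigma2 True wave SDs (> 0).
#' @param rho True correlation, strictly inside (-1, 1).
#' @param n_reps Number of replications (>= 1).
#' @param seed Master integer seed; each replication uses a deterministic
#'   substream derived from `(seed, rep_index)`.
#' @param alpha Nominal significance level for rejection-rate studies.
#'
#' @return A validated `sim_design` list.
#' @export
#' @examples
#' sim_design(n = 97, mu1 = 0, mu2 = -0.395, rho = 0.566, seed = 1)
sim_design <- function(n, mu1 = 0, mu2 = 0, sigma1 = 1.3, sigma2 = 1.3,
                       rho = 0.57, n_reps = 1L, seed = 1L, alpha = 0.05) {
  if (n < 3) abort("`n` must be at least 3.")
  if (sigma1 <= 0 || sigma2 <= 0) abort("SDs must be positive.")
  if (abs(rho) >= 1) abort("`rho` must lie strictly inside (-1, 1).")
  if (n_reps < 1) abort("`n_reps` must be at least 1.")
  if (alpha <= 0 || alpha > 1) abort("`alpha` must be in (0, 1].")
  structure(
    list(n = as.integer(n), mu1 = mu1, mu2 = mu2,
         sigma1 = sigma1, sigma2 = sigma2, rho = rho,
         n_reps = as.integer(n_reps), seed = as.integer(seed), alpha = alpha,
         rng = "Mersenne-Twister, per-replication derived substream seeds"),
    class = "sim_design"
  )
}

# Deterministic substream seed below 2^31, keyed by (seed, rep_index).
substream_seed <- function(seed, rep_index) {
  as.integer((as.double(seed) %% 2147483647 * 1103515245 +
                as.double(rep_index) * 12820163 + 1013904223) %% 2147483647)
}

#' Draw one paired sample from a simulation design
#'
#' Generates n draws from the bivariate normal with the design's moments by
#' applying the Cholesky factor of the 2x2 covariance to independent standard
#' normals. Each `rep_index` uses its own derived substream seed, so
#' replications are reproducible individually and in any order.
#'
#' @param design A [sim_design()].
#' @param rep_index Replication index, `0 <= rep_index < n_reps`.
#' @return A paired tibble with columns `y1`, `y2`.
#' @export
generate_paired <- function(design, rep_index = 0L) {
  stopifnot(inherits(design, "sim_design"))
  if (rep_index < 0 || rep_index >= design$n_reps) {
    abort("`rep_index` must satisfy 0 <= rep_index < n_reps.")
  }
  sigma <- matrix(c(design$sigma1^2,
                    design$rho * design$sigma1 * design$sigma2,
                    design$rho * design$sigma1 * design$sigma2,
                    design$sigma2^2), 2, 2)
  L <- chol(sigma)  # upper triangular: y = z %*% L has covariance sigma
  z <- withr::with_seed(
    substream_seed(design$seed, rep_index),
    matrix(rnorm(2 * design$n), ncol = 2)
  )
  y <- z %*% L
  tibble::tibble(y1 = design$mu1 + y[, 1], y2 = design$mu2 + y[, 2])
}

#' Construct a raw paired sample with exact sample moments
#'
#' Produces a synthetic dataset whose *sample* means, SDs and correlation
#' (under the n-1 convention) equal the requested values exactly, by
#' empirically whitening a random normal matrix and recolouring it with the
#' Cholesky factor of the target covariance. Useful for reconstructing a
#' dataset that is moment-equivalent to one described only by published
#' summary statistics: every fit in this package depends on the data through
#' the moments alone.
#'
#' @inheritParams moments_from_summary
#' @param seed Seed for the underlying random directions (the moments are
#'   exact for every seed).
#' @return A paired tibble with columns `y1`, `y2`.
#' @export
#' @examples
#' x <- paired_from_moments(97, mean1 = 0, sd1 = 1.9, mean2 = -0.395,
#'                          sd2 = 1.9, rho = 0.566)
#' tidy(compute_moments(x))
paired_from_moments <- function(n, mean1, sd1, mean2, sd2, rho, seed = 1L) {
  if (n < 3) abort("Need n >= 3.")
  if (abs(rho) >= 1) abort("`rho` must lie strictly inside (-1, 1).")
  z <- withr::with_seed(as.integer(seed), matrix(rnorm(2 * n), ncol = 2))
  z <- scale(z, center = TRUE, scale = FALSE)
  # whiten to exact identity sample covariance (n-1 denominator) ...
  z <- z %*% solve(chol(cov(z)))
  # ... then recolour to the target covariance and means
  sigma <- matrix(c(sd1^2, rho * sd1 * sd2, rho * sd1 * sd2, sd2^2), 2, 2)
  y <- z %*% chol(sigma)
  tibble::tibble(y1 = mean1 + y[, 1], y2 = mean2 + y[, 2])
}

#' Equivalence study: correlated LCS fit vs. classical paired t-test
#'
#' For each design, repeatedly draws samples, fits the correlated latent
#' change model with the engine and runs the classical paired t-test, and
#' records the largest absolute disagreement in the mean-change estimate and
#' its SE, plus the number of replications where the two tests disagree about
#' significance at the design's alpha (they can: the same critical ratio is
#' referred to the normal vs. the t distribution).
#'
#' @param designs A list of [sim_design()] objects (or a single design).
#' @return A tibble, one row per design: `n`, `rho`, `n_reps`,
#'   `max_abs_d_diff`, `max_abs_se_diff`, `n_decision_disagree`, `n_failed`.
#' @export
run_equivalence_study <- function(designs) {
  if (inherits(designs, "sim_design")) designs <- list(designs)
  if (length(designs) == 0) abort("`designs` must be non-empty.")
  purrr::map_dfr(designs, function(design) {
    d_diff <- se_diff <- 0
    disagree <- 0L
    failed <- 0L
    for (r in seq_len(design$n_reps) - 1L) {
      x <- generate_paired(design, r)
      res <- tryCatch({
        tt <- paired_t_test(x)
        fit <- fit_lcs_correlated(x)
        list(tt = tt, fit = fit)
      }, error = function(e) NULL)
      if (is.null(res)) { failed <- failed + 1L; next }
      d_hat <- unname(res$fit$estimates["mu_delta"])
      se_hat <- unname(res$fit$se["mu_delta"])
      d_diff <- max(d_diff, abs(d_hat - res$tt$d))
      se_diff <- max(se_diff, abs(se_hat - res$tt$se_d))
      p_norm <- unname(res$fit$p_value["mu_delta"])
      disagree <- disagree +
        as.integer((p_norm < design$alpha) != (res$tt$p.value < design$alpha))
    }
    tibble::tibble(
      n = design$n, rho = design$rho, n_reps = design$n_reps,
      max_abs_d_diff = d_diff, max_abs_se_diff = se_diff,
      n_decision_disagree = disagree, n_failed = failed
    )
  })
}

#' Monte-Carlo rejection rate of a change test
#'
#' Draws `n_reps` samples from the design and reports the fraction rejected
#' at the design's alpha, with a 95% Clopper–Pearson binomial interval. For a
#' type-I error study set `mu1 = mu2`. Test statistics are computed from the
#' sample moments with the closed-form maximum-likelihood estimators (the
#' same estimators the engine fit reproduces numerically).
#'
#' @param design A [sim_design()].
#' @param test `"ttest"` (classical paired t), `"sfm"` (self-feedback
#'   intercept, normal reference) or `"correlated"` (correlated-LCS mean
#'   change, normal reference).
#' @return A one-row tibble: `test`, `n`, `n_reps`, `alpha`, `rejection_rate`,
#'   `conf.low`, `conf.high`, `n_failed`.
#' @export
run_error_rate_study <- function(design, test = c("ttest", "sfm", "correlated")) {
  stopifnot(inherits(design, "sim_design"))
  test <- match.arg(test)
  rejected <- 0L
  failed <- 0L
  for (r in seq_len(design$n_reps) - 1L) {
    x <- generate_paired(design, r)
    p <- tryCatch({
      m <- compute_moments(x)
      switch(test,
             ttest = paired_t_test(m)$p.value,
             sfm = sfm_stats(m)$p,
             correlated = correlated_stats(m)$p)
    }, error = function(e) NA_real_)
    if (is.na(p)) { failed <- failed + 1L; next }
    rejected <- rejected + as.integer(p < design$alpha)
  }
  n_ok <- design$n_reps - failed
  ci <- stats::binom.test(rejected, n_ok)$conf.int
  tibble::tibble(
    test = test, n = design$n, n_reps = design$n_reps, alpha = design$alpha,
    rejection_rate = rejected / n_ok,
    conf.low = ci[1], conf.high = ci[2], n_failed = failed
  )
}
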