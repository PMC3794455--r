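#' Construct a two-variable path model specification
#'
#' A model specification maps a named parameter vector to the implied mean
#' vector and 2x2 covariance matrix of (Y1, Y2). At most 5 parameters can be
#' free (two means, two variances, one covariance saturate a bivariate
#' system); the model degrees of freedom are `5 - n_free`.
#'
#' @param name Model label.
#' @param free Character vector of free parameter names.
#' @param fixed Named list of fixed parameters and their values.
#' @param implied Function `theta -> list(mu = <length-2>, sigma = <2x2>)`,
#'   where `theta` is the full named vector (free + fixed).
#' @param start Function `moment_summary -> named numeric` of starting values
#'   for the free parameters (moment-based, at or near the optimum for the
#'   models in this package).
#' @param positive Names of parameters constrained positive (variances);
#'   these are log-transformed during optimization.
#'
#' @return A `model_spec` object.
#' @export
model_spec <- function(name, free, fixed = list(), implied, start,
                       positive = character()) {
  if (length(free) > 5) {
    abort("At most 5 free parameters: two means, two variances, one covariance.")
  }
  structure(
    list(name = name, free = free, fixed = fixed, implied = implied,
         start = start, positive = intersect(positive, free)),
    class = "model_spec"
  )
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s\n", x$name))
  cat(sprintf("  free (%d): %s\n", length(x$free), paste(x$free, collapse = ", ")))
  if (length(x$fixed)) {
    cat(sprintf("  fixed: %s\n",
                paste(sprintf("%s = %g", names(x$fixed), unlist(x$fixed)),
                      collapse = ", ")))
  }
  cat(sprintf("  df = %d\n", 5L - length(x$free)))
  invisible(x)
}

#' Implied mean vector and covariance matrix of a model
#'
#' Evaluates the model's structural equations at a parameter vector and
#' returns the implied moments of (Y1, Y2).
#'
#' @param spec A [model_spec()].
#' @param theta Named numeric vector of the free parameters.
#' @return A list with `mu` (length 2) and `sigma` (symmetric 2x2).
#' @export
implied_moments <- function(spec, theta) {
  stopifnot(inherits(spec, "model_spec"))
  if (!all(spec$free %in% names(theta))) {
    abort("`theta` must name every free parameter of the spec.")
  }
  full <- c(as.list(theta[spec$free]), spec$fixed)
  out <- spec$implied(full)
  out$sigma <- (out$sigma + t(out$sigma)) / 2
  out
}

#' Maximum-likelihood discrepancy between sample and implied moments
#'
#' The normal-theory fit function for mean-and-covariance structures:
#' \deqn{F = \ln|\Sigma| - \ln|S| + tr(S\Sigma^{-1}) - p +
#'   (\bar m - \mu)^\top \Sigma^{-1} (\bar m - \mu)}
#' with p = 2 observed variables. F >= 0, with equality iff the implied
#' moments equal the sample moments.
#'
#' @param summary A `moment_summary` (the sample moments).
#' @param mu Implied mean vector (length 2).
#' @param sigma Implied covariance (2x2, positive definite).
#' @return The discrepancy value (dimensionless scalar).
#' @export
ml_discrepancy <- function(summary, mu, sigma) {
  stopifnot(inherits(summary, "moment_summary"))
  S <- matrix(c(summary$var1, summary$cov12, summary$cov12, summary$var2), 2, 2)
  m <- c(summary$mean1, summary$mean2)
  det_sigma <- sigma[1, 1] * sigma[2, 2] - sigma[1, 2] * sigma[2, 1]
  if (!is.finite(det_sigma) || det_sigma <= 0) {
    abort("Implied covariance matrix is singular or indefinite.")
  }
  det_s <- S[1, 1] * S[2, 2] - S[1, 2]^2
  if (det_s <= 0) {
    abort("Sample covariance matrix is singular: the two waves are perfectly collinear.")
  }
  sigma_inv <- matrix(c(sigma[2, 2], -sigma[1, 2], -sigma[2, 1], sigma[1, 1]),
                      2, 2) / det_sigma
  resid <- m - mu
  log(det_sigma) - log(det_s) + sum(diag(S %*% sigma_inv)) - 2 +
    drop(t(resid) %*% sigma_inv %*% resid)
}

# Discrepancy as a function of the free-parameter vector; +Inf outside the
# positive-definite region so the optimizer retreats.
discrepancy_fn <- function(spec, summary) {
  function(theta) {
    names(theta) <- spec$free
    im <- implied_moments(spec, theta)
    det_sigma <- im$sigma[1, 1] * im$sigma[2, 2] - im$sigma[1, 2]^2
    if (!is.finite(det_sigma) || det_sigma <= 1e-300 ||
        im$sigma[1, 1] <= 0 || im$sigma[2, 2] <= 0) {
      return(1e10)
    }
    ml_discrepancy(summary, im$mu, im$sigma)
  }
}

# Map between natural and optimizer coordinates (log scale for variances).
to_working <- function(theta, spec) {
  theta[spec$positive] <- log(pmax(theta[spec$positive], 1e-12))
  theta
}
from_working <- function(theta, spec) {
  theta[spec$positive] <- exp(theta[spec$positive])
  theta
}

#' Fit a path model to sample moments by maximum likelihood
#'
#' Minimizes the ML discrepancy over the free parameters with a quasi-Newton
#' search (variances log-transformed to stay positive), starting from the
#' spec's moment-based values, with up to 5 jittered restarts. Standard errors
#' come from the observed information matrix of the ML log-likelihood (n-scaled)
#' at the optimum, via a central-difference Hessian. The model chi-square is
#' `(n-1) * F_min` by default (the convention under which the mean-change SE of
#' the saturated latent-change model equals the classical paired-test SE), with
#' `n * F_min` available via `chisq_scale = "n"`.
#'
#' @param spec A [model_spec()].
#' @param summary A `moment_summary`.
#' @param chisq_scale Multiplier convention for the chi-square: `"n-1"`
#'   (default) or `"n"`.
#' @param tol Convergence tolerance on the discrepancy.
#'
#' @return An `lcs_fit` object: estimates, standard errors, critical ratios
#'   (estimate/SE), two-sided normal p-values, `f_min`, `chi_square`, `df`,
#'   convergence flag and sample size. Methods: [tidy()], [glance()],
#'   [autoplot()], `print()`.
#' @export
fit_path_model <- function(spec, summary, chisq_scale = c("n-1", "n"),
                           tol = 1e-10) {
  stopifnot(inherits(spec, "model_spec"), inherits(summary, "moment_summary"))
  chisq_scale <- match.arg(chisq_scale)
  n <- summary$n
  f <- discrepancy_fn(spec, summary)
  f_working <- function(w) f(from_working(setNames(w, spec$free), spec))

  start <- spec$start(summary)[spec$free]
  best <- NULL
  for (attempt in 0:5) {
    w0 <- to_working(start, spec)
    if (attempt > 0) {
      jitter <- withr::with_seed(1000L + attempt, rnorm(length(w0), 0, 0.1))
      w0 <- w0 + jitter
    }
    res <- tryCatch(
      optim(w0, f_working, method = "BFGS",
            control = list(maxit = 500, reltol = 1e-14)),
      error = function(e) NULL
    )
    if (!is.null(res) && (is.null(best) || res$value < best$value)) best <- res
    if (!is.null(best) && best$value < 1e6) break
  }
  if (is.null(best) || best$value >= 1e6) {
    abort(sprintf("Model '%s' failed to converge after restarts.", spec$name))
  }
  theta_hat <- from_working(setNames(best$par, spec$free), spec)
  # The moment-based starts are the analytic MLE for every model in this
  # package; keep them when the search cannot genuinely improve on them, so
  # estimates are free of optimizer round-off.
  f_start <- f(start)
  if (is.finite(f_start) && f_start <= best$value + 1e-12) {
    theta_hat <- start
  }
  f_min <- max(f(theta_hat), 0)

  # Observed information of the ML log-likelihood, -l(theta) = (n/2) * G(theta)
  # with G = F + const; central-difference Hessian in the natural coordinates.
  neg_ll <- function(th) (n / 2) * f(th)
  H <- num_hessian(neg_ll, theta_hat, rel_step = 1e-5)
  se <- rep(NA_real_, length(theta_hat))
  cov_theta <- tryCatch(solve(H), error = function(e) NULL)
  if (!is.null(cov_theta)) {
    dg <- diag(cov_theta)
    se <- ifelse(dg > 0, sqrt(dg), NA_real_)
  }
  names(se) <- spec$free
  cr <- theta_hat / se
  pvals <- 2 * pnorm(-abs(cr))

  scale_factor <- if (chisq_scale == "n-1") n - 1 else n
  df <- 5L - length(spec$free)
  structure(
    list(model = spec$name, spec = spec,
         estimates = theta_hat, se = se, crit_ratio = cr, p_value = pvals,
         f_min = f_min, chi_square = scale_factor * f_min, df = df,
         converged = best$convergence == 0 && f_min < 1e6,
         n = n, chisq_scale = chisq_scale,
         denominator = summary$denominator,
         centering = attr(summary, "centering")),
    class = "lcs_fit"
  )
}

# Central-difference Hessian with relative step sizes.
num_hessian <- function(fn, x, rel_step = 1e-5) {
  k <- length(x)
  h <- rel_step * pmax(abs(x), 1)
  H <- matrix(0, k, k)
  for (i in seq_len(k)) {
    for (j in i:k) {
      if (i == j) {
        xp <- x; xp[i] <- x[i] + h[i]
        xm <- x; xm[i] <- x[i] - h[i]
        H[i, i] <- (fn(xp) - 2 * fn(x) + fn(xm)) / h[i]^2
      } else {
        xpp <- x; xpp[i] <- x[i] + h[i]; xpp[j] <- x[j] + h[j]
        xpm <- x; xpm[i] <- x[i] + h[i]; xpm[j] <- x[j] - h[j]
        xmp <- x; xmp[i] <- x[i] - h[i]; xmp[j] <- x[j] + h[j]
        xmm <- x; xmm[i] <- x[i] - h[i]; xmm[j] <- x[j] - h[j]
        H[i, j] <- H[j, i] <-
          (fn(xpp) - fn(xpm) - fn(xmp) + fn(xmm)) / (4 * h[i] * h[j])
      }
    }
  }
  H
}

#' @export
print.lcs_fit <- function(x, ...) {
  cat(sprintf("<lcs_fit> %s   (n = %d, df = %d)\n", x$model, x$n, x$df))
  tab <- tidy(x)
  print(as.data.frame(tab), row.names = FALSE, digits = 4)
  if (x$df > 0) {
    cat(sprintf("chi-square(%d) = %.4f  [scale %s],  p = %.4g\n",
                x$df, x$chi_square, x$chisq_scale,
                pchisq(x$chi_square, x$df, lower.tail = FALSE)))
  } else {
    cat(sprintf("saturated model: F_min = %.3g, chi-square = %.3g\n",
                x$f_min, x$chi_square))
  }
  invisible(x)
}

#' @describeIn fit_path_model Tidy the parameter table of a fitted model:
#'   one row per free parameter with `estimate`, `std.error`, `statistic`
#'   (the critical ratio) and `p.value` (two-sided normal).
#' @param x,object An `lcs_fit`.
#' @param ... Unused.
#' @export
tidy.lcs_fit <- function(x, ...) {
  tibble::tibble(
    term = names(x$estimates),
    estimate = unname(x$estimates),
    std.error = unname(x$se),
    statistic = unname(x$crit_ratio),
    p.value = unname(x$p_value)
  )
}

#' @describeIn fit_path_model One-row model-level summary: `chi_square`,
#'   `df`, `p.value` (upper-tail chi-square; `NA` for saturated models),
#'   `f_min`, `n`, `converged`.
#' @export
glance.lcs_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model,
    chi_square = x$chi_square,
    df = x$df,
    p.value = if (x$df > 0) pchisq(x$chi_square, x$df, lower.tail = FALSE)
              else NA_real_,
    f_min = x$f_min,
    n = x$n,
    converged = x$converged
  )
}

#' @describeIn fit_path_model Coefficient plot: point estimates with
#'   95% normal (Wald) intervals.
#' @export
autoplot.lcs_fit <- function(object, ...) {
  tab <- tidy(object)
  tab$lo <- tab$estimate - 1.959964 * tab$std.error
  tab$hi <- tab$estimate + 1.959964 * tab$std.error
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lo, xmax = .data$hi),
                            height = 0.15) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(title = object$model,
                  x = "estimate (95% Wald interval)", y = NULL) +
    ggplot2::theme_minimal()
}
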