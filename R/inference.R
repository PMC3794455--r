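#' Two-sided p-values for critical ratios and t statistics
#'
#' SEM output refers the critical ratio (estimate / SE) to the standard
#' normal distribution; the classical paired test refers the same ratio to
#' the t distribution with n - 1 df. At |CR| = 2.173 with 96 df this is the
#' 0.0297 vs. 0.032 difference: the normal p is always the smaller of the two
#' for a nonzero statistic.
#'
#' @param cr Critical ratio (finite scalar or vector).
#' @return Two-sided probability `2 * (1 - Phi(|cr|))`.
#' @export
#' @examples
#' p_normal_two_sided(-2.173)
#' p_t_two_sided(-2.173, df = 96)
p_normal_two_sided <- function(cr) {
  if (any(!is.finite(cr))) abort("`cr` must be finite.")
  2 * pnorm(-abs(cr))
}

#' @rdname p_normal_two_sided
#' @param t t statistic.
#' @param df Degrees of freedom (>= 1).
#' @export
p_t_two_sided <- function(t, df) {
  if (any(df < 1)) abort("`df` must be at least 1.")
  2 * pt(-abs(t), df = df)
}

#' Nested chi-square difference test
#'
#' Likelihood-ratio comparison of a constrained model against the model that
#' nests it: here typically the gamma = 0 latent change model against the
#' saturated self-feedback model, where the difference test on 1 df equals
#' the constrained model's own chi-square.
#'
#' @param constrained The constrained `lcs_fit` (more df).
#' @param free The nesting `lcs_fit` (fewer df).
#' @param alpha Significance level used only for the advisory `verdict`.
#'
#' @return A `chisq_diff` object with `delta_chi_square`, `delta_df`,
#'   `p.value` (upper tail of chi-square on `delta_df`) and a text `verdict`
#'   on whether the constraint is tenable at `alpha`. [tidy()] returns the
#'   one-row tibble.
#' @export
chisq_diff_test <- function(constrained, free, alpha = 0.05) {
  stopifnot(inherits(constrained, "lcs_fit"), inherits(free, "lcs_fit"))
  if (constrained$df <= free$df) {
    abort("Invalid nesting: the constrained model must have more df than the free model.")
  }
  if (!isTRUE(constrained$converged) || !isTRUE(free$converged)) {
    abort("Both fits must have converged.")
  }
  if (constrained$n != free$n) {
    abort("The two fits must come from the same data (sample sizes differ).")
  }
  delta <- constrained$chi_square - free$chi_square
  if (delta < -1e-8) {
    abort("Chi-square decreased under the constraint; the models are not nested on these data.")
  }
  delta <- max(delta, 0)
  ddf <- constrained$df - free$df
  p <- pchisq(delta, df = ddf, lower.tail = FALSE)
  structure(
    list(delta_chi_square = delta, delta_df = ddf, p.value = p,
         alpha = alpha,
         verdict = if (p < alpha) {
           sprintf("constraint rejected at alpha = %g (significant worsening of fit)", alpha)
         } else {
           sprintf("constraint tenable at alpha = %g", alpha)
         }),
    class = "chisq_diff"
  )
}

#' @export
print.chisq_diff <- function(x, ...) {
  cat(sprintf("Chi-square difference test: delta chi-square(%d) = %.4f, p = %.4g\n",
              x$delta_df, x$delta_chi_square, x$p.value))
  cat(sprintf("  %s\n", x$verdict))
  invisible(x)
}

#' @describeIn chisq_diff_test One-row tibble of the test.
#' @param x A `chisq_diff`.
#' @param ... Unused.
#' @export
tidy.chisq_diff <- function(x, ...) {
  tibble::tibble(
    delta_chi_square = x$delta_chi_square,
    delta_df = x$delta_df,
    p.value = x$p.value,
    verdict = x$verdict
  )
}
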