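#' Sensitivity of change significance to the assumed paired correlation
#'
#' When a paper reports only per-wave means and SDs, the paired correlation
#' rho — which determines the difference-score variance and hence every SE —
#' must be assumed. `rho_sweep()` re-tests the mean change over a grid of
#' assumed rho values with both the classical paired t-test and the
#' self-feedback latent change model, and locates (by bisection between the
#' bracketing grid points) the threshold rho* where each test first becomes
#' significant at `alpha`.
#'
#' With the mean change held fixed, a larger rho shrinks the difference-score
#' variance, so the t-test p-value decreases monotonically in rho; the
#' self-feedback p-value is never larger than the t-test's at the same rho
#' (the same centered point estimate, an SE shrunk by `sqrt(1 - r^2)`, and
#' a normal instead of a t reference).
#'
#' @param n Sample size.
#' @param mean1,mean2 Published wave means.
#' @param sd1,sd2 Published wave SDs.
#' @param rho_grid Ascending grid strictly inside (-1, 1). The default
#'   0.00–0.95 in steps of 0.05 mirrors a coarse exploration of plausible
#'   test–retest correlations.
#' @param alpha Significance level for the threshold search.
#'
#' @return An `lcs_sensitivity` tibble: one row per rho with `p_ttest`,
#'   `p_lcs_sfm` and logical significance marks, plus attributes
#'   `rho_star_ttest` and `rho_star_sfm` (`NA` when the curve never crosses
#'   `alpha` on the grid), `alpha`, and the design. [autoplot()] draws both
#'   curves; [format_sensitivity()] serializes the table.
#' @export
#' @examples
#' sw <- rho_sweep(n = 24, mean1 = 0, sd1 = 1, mean2 = -0.3, sd2 = 1)
#' attr(sw, "rho_star_ttest")
rho_sweep <- function(n, mean1, sd1, mean2, sd2,
                      rho_grid = seq(0, 0.95, by = 0.05), alpha = 0.05) {
  if (length(rho_grid) == 0) abort("`rho_grid` must be non-empty.")
  if (any(abs(rho_grid) >= 1)) abort("`rho_grid` must lie strictly inside (-1, 1).")
  if (is.unsorted(rho_grid, strictly = TRUE)) abort("`rho_grid` must be strictly ascending.")
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1).")

  p_ttest_at <- function(rho) {
    m <- moments_from_summary(n, mean1, sd1, mean2, sd2, rho)
    tt <- paired_t_test(m)
    tt$p.value
  }
  p_sfm_at <- function(rho) {
    m <- moments_from_summary(n, mean1, sd1, mean2, sd2, rho)
    sfm_stats(m)$p
  }

  curve <- tibble::tibble(
    rho = rho_grid,
    p_ttest = purrr::map_dbl(rho_grid, p_ttest_at),
    p_lcs_sfm = purrr::map_dbl(rho_grid, p_sfm_at)
  )
  curve$sig_ttest <- curve$p_ttest < alpha
  curve$sig_lcs_sfm <- curve$p_lcs_sfm < alpha

  out <- tibble::new_tibble(curve, class = "lcs_sensitivity")
  attr(out, "alpha") <- alpha
  attr(out, "design") <- list(n = n, mean1 = mean1, sd1 = sd1,
                              mean2 = mean2, sd2 = sd2)
  attr(out, "rho_star_ttest") <-
    locate_threshold(p_ttest_at, rho_grid, curve$p_ttest, alpha)
  attr(out, "rho_star_sfm") <-
    locate_threshold(p_sfm_at, rho_grid, curve$p_lcs_sfm, alpha)
  out
}

# Bisection between the first bracketing grid points where p crosses alpha
# from above; NA when no crossing occurs on the grid.
locate_threshold <- function(p_fun, grid, p_grid, alpha, tol = 1e-4) {
  cross <- which(p_grid[-length(p_grid)] >= alpha & p_grid[-1] < alpha)
  if (length(cross) == 0) {
    if (all(p_grid < alpha)) return(grid[1])  # already significant at grid start
    return(NA_real_)
  }
  lo <- grid[cross[1]]
  hi <- grid[cross[1] + 1]
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (p_fun(mid) < alpha) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' @export
print.lcs_sensitivity <- function(x, ...) {
  cat(format_sensitivity(x, format = "text"), sep = "\n")
  invisible(x)
}

#' Serialize a sensitivity curve
#'
#' @param curve An `lcs_sensitivity` from [rho_sweep()].
#' @param format `"text"` (aligned, with threshold footnotes), `"tsv"`, or
#'   `"json"`.
#' @return A character vector of lines (`"text"`/`"tsv"`) or a JSON string.
#'   Absent thresholds serialize as `NA`/`null`, never as zero.
#' @export
format_sensitivity <- function(curve, format = c("text", "tsv", "json")) {
  stopifnot(inherits(curve, "lcs_sensitivity"))
  format <- match.arg(format)
  alpha <- attr(curve, "alpha")
  rs_t <- attr(curve, "rho_star_ttest")
  rs_s <- attr(curve, "rho_star_sfm")
  df <- as.data.frame(curve)
  if (format == "tsv") {
    header <- paste(names(df), collapse = "\t")
    rows <- apply(df, 1, function(r) paste(r, collapse = "\t"))
    return(c(header, unname(rows)))
  }
  if (format == "json") {
    return(jsonlite::toJSON(
      list(alpha = alpha, rho_star_ttest = rs_t, rho_star_sfm = rs_s,
           curve = df),
      auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE
    ))
  }
  lines <- c(
    sprintf("Sensitivity of mean-change significance to assumed rho (alpha = %g)", alpha),
    sprintf("  %5s  %9s  %9s", "rho", "p_ttest", "p_sfm"),
    sprintf("  %5.2f  %9.4f%s  %9.4f%s", df$rho, df$p_ttest,
            ifelse(df$sig_ttest, "*", " "), df$p_lcs_sfm,
            ifelse(df$sig_lcs_sfm, "*", " ")),
    sprintf("  rho* (t-test): %s",
            if (is.na(rs_t)) "no crossing on grid" else sprintf("%.4f", rs_t)),
    sprintf("  rho* (LCS self-feedback): %s",
            if (is.na(rs_s)) "no crossing on grid" else sprintf("%.4f", rs_s)),
    "  * p < alpha"
  )
  lines
}

#' @describeIn rho_sweep p-value curves for both tests against the assumed
#'   rho, with the alpha level and located thresholds marked.
#' @param object An `lcs_sensitivity`.
#' @param ... Unused.
#' @export
autoplot.lcs_sensitivity <- function(object, ...) {
  alpha <- attr(object, "alpha")
  long <- tibble::tibble(
    rho = rep(object$rho, 2),
    p = c(object$p_ttest, object$p_lcs_sfm),
    test = rep(c("paired t-test", "LCS self-feedback"), each = nrow(object))
  )
  stars <- c(attr(object, "rho_star_ttest"), attr(object, "rho_star_sfm"))
  stars <- stars[!is.na(stars)]
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$rho, y = .data$p,
                                          colour = .data$test)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = alpha, linetype = "dashed") +
    ggplot2::labs(x = "assumed paired correlation rho",
                  y = "two-sided p-value", colour = NULL,
                  title = "Significance of the mean change vs. assumed rho") +
    ggplot2::theme_minimal()
  if (length(stars)) {
    p <- p + ggplot2::geom_vline(xintercept = stars, linetype = "dotted",
                                 colour = "grey40")
  }
  p
}
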