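#' Validate a two-wave paired sample
#'
#' Checks that a data frame holds complete paired measurements on two waves
#' (baseline `y1`, follow-up `y2`, same units), drops incomplete rows with a
#' warning, and returns a tibble with columns `y1`, `y2` and (if present) `id`.
#'
#' @param data A data frame with one row per subject.
#' @param y1,y2 Column names (strings) holding the baseline and follow-up
#'   measurements. Default `"y1"` and `"y2"`.
#' @param id Optional column name with subject labels, or `NULL`.
#'
#' @return A tibble with columns `y1`, `y2` and optionally `id`, at least 3
#'   complete rows.
#' @export
#' @examples
#' paired_sample(data.frame(y1 = c(1, 2, 3, 4), y2 = c(2, 4, 5, 7)))
paired_sample <- function(data, y1 = "y1", y2 = "y2", id = NULL) {
  if (!is.data.frame(data)) {
    abort("`data` must be a data frame of paired measurements.")
  }
  for (col in c(y1, y2)) {
    if (!col %in% names(data)) {
      abort(sprintf("Column `%s` not found in `data`.", col))
    }
  }
  out <- tibble::tibble(
    y1 = as.double(data[[y1]]),
    y2 = as.double(data[[y2]])
  )
  if (!is.null(id)) {
    if (!id %in% names(data)) abort(sprintf("Column `%s` not found in `data`.", id))
    out$id <- data[[id]]
  }
  complete <- stats::complete.cases(out$y1, out$y2)
  if (any(!complete)) {
    warn(sprintf("Dropped %d row(s) with missing values (listwise deletion).",
                 sum(!complete)))
    out <- out[complete, , drop = FALSE]
  }
  if (nrow(out) < 3L) {
    abort("A paired sample needs at least 3 complete pairs.")
  }
  out
}

#' Sample moments of a paired sample
#'
#' Computes the wave means, variances and covariance of a two-wave sample,
#' together with the derived quantities every model fit consumes: the mean
#' paired difference, the variance of the difference score, and the paired
#' correlation.
#'
#' @param data A data frame with paired columns (see [paired_sample()]).
#' @param y1,y2,id Column names passed to [paired_sample()].
#' @param denominator Denominator convention for variances and covariances:
#'   `"n-1"` (unbiased, default) or `"n"` (maximum likelihood).
#'
#' @return A `moment_summary` object: a list with `n`, `mean1`, `mean2`,
#'   `var1`, `var2`, `cov12` and `denominator`, with derived accessors
#'   available through `$d_bar`, `$var_d` and `$rho` via [moment_derived()].
#' @export
#' @examples
#' m <- compute_moments(data.frame(y1 = c(1, 2, 3, 4), y2 = c(2, 4, 5, 7)))
#' moment_derived(m)$rho
compute_moments <- function(data, y1 = "y1", y2 = "y2", id = NULL,
                            denominator = c("n-1", "n")) {
  denominator <- match.arg(denominator)
  s <- paired_sample(data, y1 = y1, y2 = y2, id = id)
  n <- nrow(s)
  scale <- if (denominator == "n-1") n - 1 else n
  m1 <- mean(s$y1)
  m2 <- mean(s$y2)
  d1 <- s$y1 - m1
  d2 <- s$y2 - m2
  v1 <- sum(d1 * d1) / scale
  v2 <- sum(d2 * d2) / scale
  c12 <- sum(d1 * d2) / scale
  if (v1 <= 0 || v2 <= 0) {
    abort("Degenerate data: zero variance in at least one wave.")
  }
  new_moment_summary(n = n, mean1 = m1, mean2 = m2, var1 = v1, var2 = v2,
                     cov12 = c12, denominator = denominator)
}

new_moment_summary <- function(n, mean1, mean2, var1, var2, cov12,
                               denominator = "n-1") {
  structure(
    list(n = as.integer(n), mean1 = mean1, mean2 = mean2,
         var1 = var1, var2 = var2, cov12 = cov12,
         denominator = denominator),
    class = "moment_summary"
  )
}

#' Build a moment summary from published summary statistics
#'
#' Reconstructs the full mean-and-covariance summary from the numbers a paper
#' typically reports (per-wave means and SDs) plus an assumed or reported
#' paired correlation. Downstream fits cannot distinguish the result from one
#' computed from raw data with those moments.
#'
#' @param n Sample size (>= 3).
#' @param mean1,mean2 Wave means.
#' @param sd1,sd2 Wave standard deviations (> 0), under `denominator`.
#' @param rho Paired correlation, strictly inside (-1, 1).
#' @param denominator Convention label recorded on the summary.
#'
#' @return A `moment_summary`.
#' @export
#' @examples
#' moments_from_summary(n = 24, mean1 = 0, sd1 = 1, mean2 = -0.3, sd2 = 1, rho = 0.5)
moments_from_summary <- function(n, mean1, sd1, mean2, sd2, rho,
                                 denominator = c("n-1", "n")) {
  denominator <- match.arg(denominator)
  if (n < 3) abort("Need n >= 3.")
  if (sd1 <= 0 || sd2 <= 0) abort("Standard deviations must be positive.")
  if (abs(rho) >= 1) abort("`rho` must lie strictly inside (-1, 1).")
  new_moment_summary(n = n, mean1 = mean1, mean2 = mean2,
                     var1 = sd1^2, var2 = sd2^2, cov12 = rho * sd1 * sd2,
                     denominator = denominator)
}

#' Derived moment quantities
#'
#' Pure functions of a moment summary: the mean paired difference
#' `d_bar = mean2 - mean1`, the difference-score variance
#' `var_d = var1 + var2 - 2 cov12`, the paired correlation `rho`, and the
#' baseline-difference covariance `cov_y1_d = cov12 - var1` with its
#' correlation `r_y1_d` (the quantity the self-feedback path estimates).
#'
#' @param m A `moment_summary`.
#' @return A named list with `d_bar`, `var_d`, `rho`, `cov_y1_d`, `r_y1_d`.
#' @export
moment_derived <- function(m) {
  stopifnot(inherits(m, "moment_summary"))
  var_d <- m$var1 + m$var2 - 2 * m$cov12
  cov_y1_d <- m$cov12 - m$var1
  r_y1_d <- if (var_d > 0) cov_y1_d / sqrt(m$var1 * var_d) else NA_real_
  list(
    d_bar = m$mean2 - m$mean1,
    var_d = var_d,
    rho = m$cov12 / sqrt(m$var1 * m$var2),
    cov_y1_d = cov_y1_d,
    r_y1_d = r_y1_d
  )
}

#' @export
print.moment_summary <- function(x, ...) {
  d <- moment_derived(x)
  cat(sprintf("<moment_summary>  n = %d  (denominator %s)\n", x$n, x$denominator))
  cat(sprintf("  means: %.4f, %.4f   d_bar = %.4f\n", x$mean1, x$mean2, d$d_bar))
  cat(sprintf("  vars:  %.4f, %.4f   cov12 = %.4f  rho = %.4f\n",
              x$var1, x$var2, x$cov12, d$rho))
  cat(sprintf("  var_d = %.4f   r(Y1, D) = %.4f\n", d$var_d, d$r_y1_d))
  invisible(x)
}

#' @export
as.data.frame.moment_summary <- function(x, ...) {
  as.data.frame(tidy.moment_summary(x))
}

#' @export
tidy.moment_summary <- function(x, ...) {
  d <- moment_derived(x)
  tibble::tibble(
    n = x$n, mean1 = x$mean1, mean2 = x$mean2,
    var1 = x$var1, var2 = x$var2, cov12 = x$cov12,
    d_bar = d$d_bar, var_d = d$var_d, rho = d$rho,
    denominator = x$denominator
  )
}

#' Center both waves on the wave-1 mean
#'
#' Subtracts the baseline mean from both columns, so that the centered wave-2
#' mean equals the mean paired difference and the self-feedback intercept is
#' interpretable as the mean change at the average baseline. Differences and
#' all (co)variances are unchanged.
#'
#' @inheritParams paired_sample
#' @return The centered tibble, with a `centering` attribute: a list with
#'   `offset` (the wave-1 mean subtracted) and `applied = TRUE`. Retrieve it
#'   with [centering_record()].
#' @export
#' @examples
#' centered <- center_on_wave1(data.frame(y1 = c(1, 2, 3), y2 = c(2, 3, 4)))
#' centering_record(centered)
center_on_wave1 <- function(data, y1 = "y1", y2 = "y2", id = NULL) {
  s <- paired_sample(data, y1 = y1, y2 = y2, id = id)
  offset <- mean(s$y1)
  s$y1 <- s$y1 - offset
  s$y2 <- s$y2 - offset
  attr(s, "centering") <- list(offset = offset, applied = TRUE)
  s
}

#' @rdname center_on_wave1
#' @param data A tibble returned by [center_on_wave1()] (or any data frame).
#' @export
centering_record <- function(data) {
  attr(data, "centering") %||% list(offset = 0, applied = FALSE)
}

# Center a moment summary: shift both means by -mean1 (moments untouched).
center_moments <- function(m) {
  stopifnot(inherits(m, "moment_summary"))
  offset <- m$mean1
  m$mean2 <- m$mean2 - offset
  m$mean1 <- 0
  attr(m, "centering") <- list(offset = offset, applied = TRUE)
  m
}

# Difference-score variance rescaled to the unbiased (n-1) convention,
# regardless of the convention the summary was computed under. The classical
# paired test is defined with the unbiased variance.
var_d_unbiased <- function(m) {
  v <- moment_derived(m)$var_d
  if (identical(m$denominator, "n")) v * m$n / (m$n - 1) else v
}

#' Read a two-column paired CSV file
#'
#' Expects a header row; the measurement columns default to `y1`, `y2` and can
#' be renamed via arguments. Decimal point, UTF-8.
#'
#' @param path Path to the CSV file.
#' @inheritParams paired_sample
#' @return A validated paired tibble (see [paired_sample()]).
#' @export
read_paired_csv <- function(path, y1 = "y1", y2 = "y2", id = NULL) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  paired_sample(raw, y1 = y1, y2 = y2, id = id)
}

#' Read a summary-statistics configuration (YAML or JSON)
#'
#' The file must provide `n`, `mean1`, `sd1`, `mean2`, `sd2`, and either a
#' scalar `rho` or a `rho_grid` block with `min`, `max`, `step`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A list with the parsed fields; `rho_grid` (if given) is expanded to
#'   a numeric vector.
#' @export
read_summary_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  # YAML 1.1 parses a bare `n` key as boolean FALSE; map it back.
  if (!"n" %in% names(cfg) && "FALSE" %in% names(cfg)) {
    names(cfg)[names(cfg) == "FALSE"] <- "n"
  }
  needed <- c("n", "mean1", "sd1", "mean2", "sd2")
  missing <- setdiff(needed, names(cfg))
  if (length(missing)) {
    abort(sprintf("Summary config is missing field(s): %s",
                  paste(missing, collapse = ", ")))
  }
  if (is.null(cfg$rho) && is.null(cfg$rho_grid)) {
    abort("Summary config needs either `rho` or `rho_grid` (min, max, step).")
  }
  if (!is.null(cfg$rho_grid)) {
    g <- cfg$rho_grid
    if (!all(c("min", "max", "step") %in% names(g))) {
      abort("`rho_grid` needs fields min, max, step.")
    }
    cfg$rho_grid <- seq(g$min, g$max, by = g$step)
  }
  cfg
}

# Coerce flexible user input (data frame, moment_summary) to a moment_summary.
as_moments <- function(x, denominator = "n-1", y1 = "y1", y2 = "y2") {
  if (inherits(x, "moment_summary")) return(x)
  if (is.data.frame(x)) return(compute_moments(x, y1 = y1, y2 = y2,
                                               denominator = denominator))
  abort("Expected a data frame of paired measurements or a `moment_summary`.")
}
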