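#' Run the full four-model change analysis
#'
#' Executes the complete sequence on one paired dataset: the classical paired
#' t-test, the correlated latent change model (its SEM twin), the
#' self-feedback latent change model, the gamma = 0 constrained model, and
#' the nested chi-square difference test of the no-self-feedback constraint.
#'
#' @param x A data frame of paired measurements, a path to a two-column CSV
#'   file, or a `moment_summary`.
#' @param center Center both waves on the wave-1 mean before the LCS fits
#'   (default `TRUE`).
#' @param alpha Significance level used in verdicts.
#' @param denominator,chisq_scale Convention flags, see [compute_moments()]
#'   and [fit_path_model()].
#' @param y1,y2,id Column names when `x` is a data frame or CSV path.
#'
#' @return An `lcs_report`: input provenance, the centering record, the four
#'   model results, the difference test, and the convention flags in force.
#'   Methods: `print()`, [tidy()] (stacked coefficient table with a `model`
#'   column), [write_report()].
#' @export
#' @examples
#' toy <- data.frame(y1 = c(1, 2, 3, 4), y2 = c(2, 4, 5, 7))
#' rep <- run_full_analysis(toy)
#' tidy(rep)
run_full_analysis <- function(x, center = TRUE, alpha = 0.05,
                              denominator = c("n-1", "n"),
                              chisq_scale = c("n-1", "n"),
                              y1 = "y1", y2 = "y2", id = NULL) {
  denominator <- match.arg(denominator)
  chisq_scale <- match.arg(chisq_scale)

  source_label <- "moment summary"
  dropped <- 0L
  if (is.character(x) && length(x) == 1L) {
    source_label <- x
    if (!file.exists(x)) abort(sprintf("File not found: %s", x))
    x <- readr::read_csv(x, show_col_types = FALSE, progress = FALSE)
  } else if (is.data.frame(x)) {
    source_label <- "in-memory data frame"
  }
  if (is.data.frame(x)) {
    n_in <- nrow(x)
    x <- withCallingHandlers(
      paired_sample(x, y1 = y1, y2 = y2, id = id),
      warning = function(w) invokeRestart("muffleWarning")
    )
    dropped <- n_in - nrow(x)
    if (dropped > 0) {
      warn(sprintf("Dropped %d incomplete row(s) before analysis.", dropped))
    }
    y1 <- "y1"; y2 <- "y2"
  }
  m <- as_moments(x, denominator = denominator, y1 = y1, y2 = y2)
  m_fit <- if (center) center_moments(m) else m

  ttest <- paired_t_test(m)
  fit_corr <- fit_path_model(spec_lcs_correlated(), m_fit, chisq_scale = chisq_scale)
  fit_sfm <- fit_path_model(spec_lcs_sfm(), m_fit, chisq_scale = chisq_scale)
  fit_g0 <- fit_path_model(spec_lcs_no_sfm(), m_fit, chisq_scale = chisq_scale)
  diff_test <- chisq_diff_test(fit_g0, fit_sfm, alpha = alpha)

  structure(
    list(
      input = list(source = source_label, n = m$n, rows_dropped = dropped),
      centering = list(applied = center,
                       offset = if (center) m$mean1 else 0),
      moments = m,
      ttest = ttest,
      lcs_correlated = fit_corr,
      lcs_sfm = fit_sfm,
      lcs_no_sfm = fit_g0,
      chisq_diff = diff_test,
      conventions = list(denominator = denominator, chisq_scale = chisq_scale,
                         alpha = alpha),
      package_version = as.character(packageVersion("pairedlcs"))
    ),
    class = "lcs_report"
  )
}

#' @export
print.lcs_report <- function(x, ...) {
  cat("== Paired-change analysis ==\n")
  cat(sprintf("input: %s  (n = %d, %d row(s) dropped)\n",
              x$input$source, x$input$n, x$input$rows_dropped))
  cat(sprintf("centering on wave-1 mean: %s (offset %.4f)\n",
              if (x$centering$applied) "yes" else "no", x$centering$offset))
  cat(sprintf("conventions: denominator %s, chi-square scale %s, alpha %g\n\n",
              x$conventions$denominator, x$conventions$chisq_scale,
              x$conventions$alpha))
  print(x$ttest); cat("\n")
  print(x$lcs_correlated); cat("\n")
  print(x$lcs_sfm); cat("\n")
  print(x$lcs_no_sfm); cat("\n")
  print(x$chisq_diff)
  invisible(x)
}

#' @describeIn run_full_analysis Stacked coefficient table of the three
#'   latent change fits plus the classical test, with a `model` column.
#' @param x An `lcs_report`.
#' @param ... Unused.
#' @export
tidy.lcs_report <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(tidy(x$ttest)[, c("term", "estimate", "std.error",
                                    "statistic", "p.value")],
                  model = "paired t-test", .before = 1),
    dplyr::mutate(tidy(x$lcs_correlated), model = x$lcs_correlated$model,
                  .before = 1),
    dplyr::mutate(tidy(x$lcs_sfm), model = x$lcs_sfm$model, .before = 1),
    dplyr::mutate(tidy(x$lcs_no_sfm), model = x$lcs_no_sfm$model, .before = 1)
  )
}

# Flatten a report to plain lists for lossless JSON serialization.
report_to_list <- function(report) {
  fit_block <- function(f) {
    list(model = f$model,
         estimates = as.list(f$estimates),
         std_errors = as.list(f$se),
         crit_ratios = as.list(f$crit_ratio),
         p_values = as.list(f$p_value),
         f_min = f$f_min, chi_square = f$chi_square, df = f$df,
         converged = f$converged, n = f$n)
  }
  list(
    input = report$input,
    centering = report$centering,
    conventions = report$conventions,
    ttest = list(d = report$ttest$d, se_d = report$ttest$se_d,
                 t = report$ttest$statistic, df = report$ttest$df,
                 p_value = report$ttest$p.value, rho = report$ttest$rho,
                 n = report$ttest$n),
    lcs_correlated = fit_block(report$lcs_correlated),
    lcs_sfm = fit_block(report$lcs_sfm),
    lcs_no_sfm = fit_block(report$lcs_no_sfm),
    chisq_diff = list(delta_chi_square = report$chisq_diff$delta_chi_square,
                      delta_df = report$chisq_diff$delta_df,
                      p_value = report$chisq_diff$p.value,
                      verdict = report$chisq_diff$verdict),
    package_version = report$package_version
  )
}

#' Write an analysis report to disk
#'
#' JSON output serializes every number at full precision and round-trips
#' losslessly through [jsonlite::read_json()]; text output is the same
#' aligned report `print()` shows, including the convention flags. Absent
#' fields serialize as JSON `null`, never as zero.
#'
#' @param report An `lcs_report` from [run_full_analysis()].
#' @param path Output file path.
#' @param format `"json"` or `"text"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("json", "text")) {
  stopifnot(inherits(report, "lcs_report"))
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(report_to_list(report), path,
                         auto_unbox = TRUE, digits = NA, na = "null",
                         pretty = TRUE)
  } else {
    txt <- utils::capture.output(print(report))
    writeLines(txt, path)
  }
  invisible(path)
}
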