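#' Plot county-by-year screening coverage
#'
#' Line plot of the coverage fraction per county over calendar years with
#' the inclusion threshold drawn as a dashed reference, mirroring the
#' regional computerization ramp-up of electronic screening records.
#'
#' @param cells Coverage table from [coverage_table()].
#' @param threshold Inclusion threshold to display.
#' @return A ggplot object.
#' @export
plot_coverage <- function(cells, threshold = 0.8) {
  check_columns(cells, c("county", "year", "coverage"), "coverage table")
  ggplot2::ggplot(cells, ggplot2::aes(.data$year, .data$coverage,
                                      colour = .data$county)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.0f%%", 100 * x),
                                limits = c(0, 1)) +
    ggplot2::labs(x = "Year", y = "Births with screening records",
                  colour = "County") +
    ggplot2::theme_minimal()
}

#' Plot per-year antibody prevalence trends
#'
#' @param yearly Output of [yearly_prevalence()].
#' @return A ggplot object.
#' @export
plot_prevalence_trends <- function(yearly) {
  check_columns(yearly, c("stratum", "year", "rate_per_10k"), "yearly table")
  ggplot2::ggplot(yearly, ggplot2::aes(.data$year, .data$rate_per_10k,
                                       colour = .data$stratum)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "Year", y = "Prevalence per 10,000 births",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot validation metrics with confidence intervals
#'
#' @param object An `rbc_validation` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rbc_validation <- function(object, ...) {
  m <- object$metrics
  ggplot2::ggplot(m, ggplot2::aes(.data$metric, .data$estimate)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_lower,
                                        ymax = .data$ci_upper), width = 0.15) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Estimate (95% CI)") +
    ggplot2::theme_minimal()
}
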