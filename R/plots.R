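#' Plot a quarterly indicator series
#'
#' Line plot of a quarterly series by sector, one facet per indicator,
#' optionally overlaying the fitted OLS trend line.
#'
#' @param series A tidy series tibble (`sector, indicator, quarter_index,
#'   value`), e.g. from [quarterly_rate()] or [published_series()].
#' @param trend Overlay the fitted trend line (default TRUE).
#' @return A ggplot object.
#' @export
plot_quarterly <- function(series, trend = TRUE) {
  p <- ggplot2::ggplot(series,
                       ggplot2::aes(x = .data$quarter_index + 1,
                                    y = .data$value,
                                    colour = .data$sector)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~indicator, scales = "free_y") +
    ggplot2::labs(x = "Quarter number", y = "Value", colour = "Sector") +
    ggplot2::theme_minimal()
  if (trend) {
    p <- p + ggplot2::geom_smooth(method = "lm", formula = y ~ x,
                                  se = FALSE, linewidth = 0.4,
                                  linetype = "dashed")
  }
  p
}

#' Autoplot a trend fit
#'
#' The underlying quarterly points with the fitted lines, one facet per
#' indicator.
#'
#' @param object A `trend_fit` from [fit_trend()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot trend_fit
#' @export
autoplot.trend_fit <- function(object, ...) {
  plot_quarterly(object$series, trend = TRUE)
}

#' Plot cross-setting concordance
#'
#' Scatter of paired association statistics from two care settings with the
#' least-squares line and the R-squared annotation.
#'
#' @param stats_a,stats_b Named statistic vectors (see [statistic_list()]).
#' @param labels Length-2 axis labels.
#' @return A ggplot object.
#' @export
plot_concordance <- function(stats_a, stats_b, labels = c("CCC", "LTC")) {
  shared <- intersect(names(stats_a), names(stats_b))
  d <- tibble::tibble(a = stats_a[shared], b = stats_b[shared])
  d <- d[stats::complete.cases(d), ]
  r2 <- cross_setting_concordance(stats_a, stats_b)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$a, y = .data$b)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5) +
    ggplot2::labs(x = labels[1], y = labels[2],
                  title = sprintf("Cross-setting concordance, R² = %.2f",
                                  r2)) +
    ggplot2::theme_minimal()
}
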