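# Plot-ready ggplot2 views of the main result tables.

#' Forest plot of reporting odds ratios
#'
#' @param stats Tibble with `ror`, `ror_lo`, `ror_hi` and a labelling
#'   column (`event` by default).
#' @param label Column used for the y axis.
#' @return A ggplot object (log-scaled x axis, reference line at 1).
#' @export
plot_signal_forest <- function(stats, label = "event") {
  stats <- stats[!is.na(stats$ror) & !is.na(stats$ror_lo), , drop = FALSE]
  ggplot2::ggplot(
    stats,
    ggplot2::aes(x = .data$ror,
                 y = stats::reorder(.data[[label]], .data$ror))
  ) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey40") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ror_lo, xmax = .data$ror_hi), height = 0.2
    ) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Reporting odds ratio (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Annual report counts per drug
#'
#' @param counts Tibble from [annual_counts()].
#' @return A ggplot line chart.
#' @export
plot_annual_counts <- function(counts) {
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$year, y = .data$n,
                                       colour = .data$drug)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "Year", y = "Event reports", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Binned onset distribution per drug
#'
#' @param bins Tibble from [onset_bin_table()].
#' @return A ggplot bar chart of onset-day bins.
#' @export
plot_onset_bins <- function(bins) {
  bins$bin <- factor(bins$bin, levels = unique(bins$bin))
  ggplot2::ggplot(bins, ggplot2::aes(x = .data$bin, y = .data$pct,
                                     fill = .data$drug)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "Time to onset (days)", y = "Share of reports (%)",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn fit_weibull_onset Density overlay of a fitted Weibull
#'   onset model; pass the observed times to add their histogram.
#' @param object A `weibull_fit`.
#' @param times Optional observed onset days for the histogram layer.
#' @param ... Ignored.
#' @export
autoplot.weibull_fit <- function(object, times = NULL, ...) {
  upper <- if (!is.null(times)) max(times) else
    qgamma(0.99, shape = 1) * object$alpha * 3
  grid <- tibble::tibble(
    t = seq(0.5, upper, length.out = 400)
  )
  grid$density <- stats::dweibull(grid$t, shape = object$beta,
                                  scale = object$alpha)
  p <- ggplot2::ggplot(grid, ggplot2::aes(x = .data$t, y = .data$density))
  if (!is.null(times)) {
    p <- p + ggplot2::geom_histogram(
      data = tibble::tibble(t = times),
      ggplot2::aes(x = .data$t, y = ggplot2::after_stat(density)),
      inherit.aes = FALSE, bins = 40, fill = "grey80", colour = "grey60"
    )
  }
  p + ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "Time to onset (days)", y = "Density") +
    ggplot2::theme_minimal()
}
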