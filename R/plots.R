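#' Plot a kymograph
#'
#' Raster display with position on the x axis and time running downwards,
#' the conventional kymograph orientation.
#'
#' @param object a [kymograph()].
#' @param ... unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.kymograph <- function(object, ...) {
  df <- tidyr::expand_grid(row = seq_len(nrow(object$values)),
                           col = seq_len(ncol(object$values)))
  df$intensity <- as.vector(object$values)[(df$col - 1) * nrow(object$values) + df$row]
  ggplot2::ggplot(df, ggplot2::aes(x = (.data$col - 0.5) * object$px_um,
                                   y = (.data$row - 0.5) * object$dt_s,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::labs(x = "position (µm)", y = "time (s)", fill = "AU") +
    ggplot2::theme_minimal()
}

#' Longitudinal MEA activity plot
#'
#' One line per well across days in vitro for a chosen well-level
#' metric.
#'
#' @param summaries tibble of [summarize_well()] rows (needs `well_id`,
#'   `div` and the metric column).
#' @param metric metric column (tidy-eval), default `mfr`.
#' @return A ggplot object.
#' @export
plot_well_activity <- function(summaries, metric = mfr) {
  ggplot2::ggplot(summaries,
                  ggplot2::aes(x = .data$div, y = {{ metric }},
                               group = .data$well_id, colour = .data$well_id)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "days in vitro") +
    ggplot2::theme_classic()
}
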