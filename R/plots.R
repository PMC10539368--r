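# ggplot2 display methods for result objects.

#' @export
autoplot.bq_response_trace <- function(object, ...) {
  onset <- attr(object, "stimulus_onset")
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$dff)) +
    ggplot2::geom_line(linewidth = 0.6) +
    ggplot2::labs(x = "Time (s)", y = expression(Delta * F / F[0])) +
    ggplot2::theme_minimal()
  if (!is.null(onset)) {
    p <- p + ggplot2::geom_vline(xintercept = onset,
                                 linetype = "dashed", colour = "grey40")
  }
  p
}

#' @export
autoplot.bq_input_map <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$col, y = .data$row,
                                       fill = .data$amplitude)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "Summed EPSC (pA)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Stimulation column", y = "Stimulation row (pia up)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.bq_profile <- function(object, ...) {
  ycol <- if ("log2fc" %in% names(object)) "log2fc" else
    if ("norm" %in% names(object)) "norm" else "mean"
  ggplot2::ggplot(object, ggplot2::aes(x = .data$position,
                                       y = .data[[ycol]])) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "Normalized position", y = ycol) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.bq_ioc <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$region, y = .data$ioc)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "Index of connectivity") +
    ggplot2::theme_minimal()
}

#' Plot a matrix (projection, heatmap fraction) as a raster
#'
#' @param m Numeric matrix.
#' @param name Fill legend title.
#' @return A ggplot object.
#' @export
plot_matrix <- function(m, name = "value") {
  df <- tidyr::expand_grid(y = seq_len(nrow(m)), x = seq_len(ncol(m)))
  df$value <- as.numeric(t(m))[(df$y - 1) * ncol(m) + df$x]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = name) +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}
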