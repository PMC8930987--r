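# ggplot2 display methods for the package's result types.

#' Plot an image pattern
#'
#' @param object An `image_pattern`.
#' @param ... Unused.
#' @return A ggplot raster plot.
#' @export
autoplot.image_pattern <- function(object, ...) {
  img <- object$intensities
  df <- tidyr::expand_grid(row = seq_len(nrow(img)), col = seq_len(ncol(img)))
  df$value <- as.vector(t(img))[(df$row - 1) * ncol(img) + df$col]
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 1)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(fill = "I", x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a waveform trace
#'
#' @param object A `waveform`.
#' @param ... Unused.
#' @return A ggplot line plot of detector signal against time (ns).
#' @export
autoplot.waveform <- function(object, ...) {
  t_ns <- (object$t0_ps + (seq_along(object$samples) - 1) * object$dt_ps) /
    1000
  df <- tibble::tibble(t_ns = t_ns, value = object$samples)
  ggplot2::ggplot(df, ggplot2::aes(.data$t_ns, .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (ns)", y = "detector signal (a.u.)") +
    ggplot2::theme_minimal()
}

#' Plot a study result
#'
#' Dispatches on the study type: fidelity against fiber length
#' (length_ablation), fidelity against perturbation strength by training
#' scheme (robustness), contrast per bar pitch (resolution), frame rate per
#' length (frame_rate).
#'
#' @param object A `study_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.study_result <- function(object, ...) {
  tb <- object$table
  switch(object$study,
    length_ablation = ggplot2::ggplot(
      tb, ggplot2::aes(.data$length_m, .data$fidelity_mean)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::labs(x = "fiber length (m)", y = "mean fidelity") +
      ggplot2::theme_minimal(),
    robustness = ggplot2::ggplot(
      tb, ggplot2::aes(.data$strength, .data$fidelity_mean,
                       colour = .data$scheme)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::labs(x = "perturbation strength", y = "mean fidelity") +
      ggplot2::theme_minimal(),
    resolution = ggplot2::ggplot(
      tb, ggplot2::aes(factor(.data$pitch_um), .data$contrast,
                       fill = .data$orientation)) +
      ggplot2::geom_col(position = "dodge") +
      ggplot2::labs(x = "bar pitch (um)", y = "Michelson contrast") +
      ggplot2::theme_minimal(),
    frame_rate = ggplot2::ggplot(
      tb, ggplot2::aes(.data$length_m, .data$max_frame_rate_mhz)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::labs(x = "fiber length (m)", y = "max frame rate (MHz)") +
      ggplot2::theme_minimal(),
    stop("no plot defined for study ", object$study))
}

#' Plot per-mode group delays
#'
#' @param object A `mode_basis`.
#' @param ... Unused.
#' @return A ggplot of per-mode delay (ns over the fiber length) against
#'   mode index, coloured by azimuthal order.
#' @export
autoplot.mode_basis <- function(object, ...) {
  tb <- group_delays(object)
  tb$index <- seq_len(nrow(tb))
  ggplot2::ggplot(tb, ggplot2::aes(.data$index, .data$delay_ps / 1000,
                                   colour = factor(.data$l))) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "mode (sorted by delay)", y = "group delay (ns)",
                  colour = "l") +
    ggplot2::theme_minimal()
}
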