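# ggplot2 visualization helpers.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

image_to_long <- function(values) {
  tibble::tibble(
    row = rep(seq_len(nrow(values)), ncol(values)),
    col = rep(seq_len(ncol(values)), each = nrow(values)),
    value = as.vector(values)
  )
}

#' @export
autoplot.ion_image <- function(object, ...) {
  df <- image_to_long(object$values)
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(na.value = "grey20",
                                  name = "intensity") +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      title = sprintf("m/z %.4f ± %.4g Da", object$target_mz,
                      object$tolerance),
      x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.concentration_map <- function(object, ...) {
  df <- image_to_long(object$values)
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(na.value = "grey20", name = "ng/g") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("Drug concentration (m/z %.4f)",
                                  object$target_mz),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a calibration series with its fitted line
#'
#' @param series a [calibration_series()].
#' @param model optional [fit_calibration()] model to overlay.
#' @return A ggplot object.
#' @export
plot_calibration <- function(series, model = NULL) {
  p <- ggplot2::ggplot(series, ggplot2::aes(.data$nominal_conc,
                                            .data$mean_intensity)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "nominal concentration (ng/g)",
                  y = "mean intensity (a.u.)",
                  title = "Tissue-mimetic calibration series") +
    ggplot2::theme_minimal()
  if (!is.null(model)) {
    p <- p + ggplot2::geom_abline(slope = model$slope,
                                  intercept = model$intercept,
                                  color = "firebrick") +
      ggplot2::labs(subtitle = sprintf("intensity = %.3g conc + %.3g (r² = %.4f)",
                                       model$slope, model$intercept,
                                       model$r_squared))
  }
  p
}

#' @export
autoplot.correlation_report <- function(object, ...) {
  df <- dplyr::mutate(object,
                      pair = paste(.data$channel_a, .data$channel_b,
                                   sep = " / "))
  ggplot2::ggplot(df, ggplot2::aes(.data$region, .data$pair,
                                   fill = .data$r_raw)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$r_raw)),
                       size = 3) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), name = "Pearson r") +
    ggplot2::labs(x = NULL, y = NULL, title = "Ion-image colocalization") +
    ggplot2::theme_minimal()
}

#' Plot ROI statistics as a boxplot-style summary
#'
#' One bar per region showing mean with an IQR ribbon, the per-region view
#' used for regional drug-intensity comparisons.
#'
#' @param stats tibble of [roi_statistics()] rows.
#' @return A ggplot object.
#' @export
plot_roi_stats <- function(stats) {
  ggplot2::ggplot(stats, ggplot2::aes(.data$label, .data$mean)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$iqr / 2,
                                        ymax = .data$mean + .data$iqr / 2),
                           width = 0.2) +
    ggplot2::labs(x = NULL, y = unique(stats$units)[1],
                  title = "Regional summary") +
    ggplot2::theme_minimal()
}
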