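# QC figures: growth curves, volume loss, growth-rate distributions,
# plate heatmaps.

#' @method autoplot volume_loss_fit
#' @export
autoplot.volume_loss_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$time_h, y = .data$normalized)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = 1 - object$slope * object$t0,
                         slope = object$slope, colour = "steelblue") +
    ggplot2::labs(
      x = "Time (h)", y = "Dye OD450 (normalized to first timepoint)",
      title = sprintf("Volume loss: %.3g per hour (r² = %.3f)",
                      object$slope, object$r2)
    )
}

#' @method autoplot growth_fit
#' @export
autoplot.growth_fit <- function(object, ...) {
  d <- tibble::tibble(time_h = object$time_h, od = object$od)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$time_h, y = .data$od)) +
    ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Time (h)", y = "OD600 (log scale)")
  if (object$window$found) {
    p <- p + ggplot2::annotate("rect",
      xmin = object$window$t_start, xmax = object$window$t_end,
      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "steelblue") +
      ggplot2::labs(title = sprintf("mu_max = %.3f h⁻¹ (%s)",
                                    object$mu_max, object$method))
  }
  p
}

#' Plot all growth curves of a plate
#'
#' @param series Series tibble with `time_h` and `od600_corrected` (or
#'   `od600_raw`).
#' @param colour_by Column mapped to colour (default `"organism"`).
#' @return A ggplot object (log OD600 versus time, one line per well).
#' @export
plot_growth_curves <- function(series, colour_by = "organism") {
  od_col <- if ("od600_corrected" %in% names(series)) "od600_corrected" else "od600_raw"
  ggplot2::ggplot(series, ggplot2::aes(
    x = .data$time_h, y = .data[[od_col]],
    group = interaction(.data$plate_id, .data$well),
    colour = .data[[colour_by]]
  )) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Time (h)", y = "Corrected OD600 (log scale)")
}

#' Histogram of per-well maximum growth rates
#'
#' @param mu_table Per-well tibble from [fit_mu_max()].
#' @return A ggplot object.
#' @export
plot_mu_distribution <- function(mu_table) {
  d <- dplyr::filter(mu_table, .data$role == "sample", !.data$no_growth)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mu_max, fill = .data$organism)) +
    ggplot2::geom_histogram(bins = 30, alpha = 0.7, position = "identity") +
    ggplot2::labs(x = expression(mu[max] ~ (h^-1)), y = "Wells")
}

#' Plate heatmap of a per-well quantity
#'
#' Renders any per-well value (energy charge, growth rate, CV, ...) on the
#' 8 x 12 plate grid.
#'
#' @param data Tibble with columns `well` and the value column.
#' @param value Name of the value column (default `"value"`).
#' @return A ggplot object.
#' @export
plot_plate_heatmap <- function(data, value = "value") {
  pos <- well_position(data$well)
  d <- dplyr::bind_cols(data, pos[c("row", "col")])
  ggplot2::ggplot(d, ggplot2::aes(x = .data$col, y = .data$row,
                                  fill = .data[[value]])) +
    ggplot2::geom_tile(colour = "grey80") +
    ggplot2::scale_y_reverse(breaks = 1:8, labels = LETTERS[1:8]) +
    ggplot2::scale_x_continuous(breaks = 1:12, position = "top") +
    ggplot2::labs(x = NULL, y = NULL, fill = value) +
    ggplot2::coord_fixed()
}
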