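#' Plot a radial intensity profile
#'
#' Mean intensity versus distance from the colony edge, with a +/- SEM
#' ribbon where defined.
#'
#' @param object A `radial_profile` from [bin_radial()] or
#'   [average_profiles()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method autoplot radial_profile
#' @export
autoplot.radial_profile <- function(object, ...) {
  df <- dplyr::mutate(object, mid = (.data$bin_lo_um + .data$bin_hi_um) / 2)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = mean)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_point(na.rm = TRUE, size = 1) +
    ggplot2::labs(x = "Distance from colony edge (µm)",
                  y = "Mean intensity (a.u.)",
                  title = df$channel[1]) +
    ggplot2::theme_minimal()
  if (any(!is.na(df$sem))) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = mean - .data$sem, ymax = mean + .data$sem),
      alpha = 0.2, na.rm = TRUE)
  }
  p
}

#' Heatmap of a duration-by-delay screen grid
#'
#' @param object A `screen_grid` from [build_grid()].
#' @param value Column to map to fill: `"mean"` (default) or
#'   `"normalized"`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method autoplot screen_grid
#' @export
autoplot.screen_grid <- function(object, value = "mean", ...) {
  df <- dplyr::filter(object, .data$valid)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$delay_h),
                                   y = factor(.data$duration_h),
                                   fill = .data[[value]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "#1a9850", high = "#d73027",
                                 na.value = "grey85") +
    ggplot2::labs(x = "WNT onset delay (h)", y = "WNT duration (h)",
                  fill = value) +
    ggplot2::theme_minimal()
}

#' Plot a light-driven signaling time series
#'
#' Non-membrane beta-catenin level over time with the light-ON intervals
#' shaded.
#'
#' @param object A `signaling_series` from [simulate_bcat_series()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method autoplot signaling_series
#' @export
autoplot.signaling_series <- function(object, ...) {
  sched <- attr(object, "schedule")
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$t_h, y = .data$value))
  if (!is.null(sched) && nrow(sched)) {
    p <- p + ggplot2::geom_rect(
      data = as.data.frame(sched), inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$start_h, xmax = .data$end_h,
                   ymin = -Inf, ymax = Inf),
      fill = "#74add1", alpha = 0.3)
  }
  p + ggplot2::geom_line() +
    ggplot2::labs(x = "Time (h)", y = "Non-membrane β-catenin (a.u.)") +
    ggplot2::theme_minimal()
}

#' Scatter plot of a nucleus table coloured by a marker
#'
#' @param table Nucleus table with `x_um`, `y_um`.
#' @param channel Marker column to colour by.
#' @return A ggplot.
#' @export
plot_colony <- function(table, channel = "BRA") {
  ggplot2::ggplot(table, ggplot2::aes(x = .data$x_um, y = .data$y_um,
                                      colour = .data[[channel]])) +
    ggplot2::geom_point(size = 1) +
    ggplot2::coord_equal() +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)", colour = channel) +
    ggplot2::theme_minimal()
}
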