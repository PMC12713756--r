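#' Tidy a density model
#'
#' @param x A [density_model()].
#' @param ... Unused.
#' @return A tibble with one row per parameter.
#' @exportS3Method tidy density_model
#' @export
tidy.density_model <- function(x, ...) {
  tibble::tibble(term = c("rho0", "doubling_time"),
                 estimate = c(x$rho0, x$doubling_time),
                 unit = c("cells/mm^2", "h"))
}

#' One-row summary of a density model
#'
#' @param x A [density_model()].
#' @param ... Unused.
#' @return A tibble with the model parameters and the density extrapolated
#'   to 48 h (the usual differentiation endpoint).
#' @exportS3Method glance density_model
#' @export
glance.density_model <- function(x, ...) {
  tibble::tibble(rho0 = x$rho0, doubling_time = x$doubling_time,
                 density_48h = infer_density(48, x))
}

#' @export
predict.density_model <- function(object, t = seq(0, 48, by = 6), ...) {
  tibble::tibble(t_h = t, density = infer_density(t, object))
}

#' Tidy a screen grid into a plain long tibble
#'
#' @param x A [build_grid()] result.
#' @param ... Unused.
#' @return A tibble, one row per (delay, duration, arm) cell.
#' @exportS3Method tidy screen_grid
#' @export
tidy.screen_grid <- function(x, ...) {
  tibble::as_tibble(x)
}

#' One-row summary of a screen grid
#'
#' @param x A [build_grid()] result.
#' @param ... Unused.
#' @return A tibble: number of conditions, replicate range, and the peak
#'   cell.
#' @exportS3Method glance screen_grid
#' @export
glance.screen_grid <- function(x, ...) {
  def <- dplyr::filter(x, .data$valid, !is.na(mean))
  peak <- def[which.max(def$mean), ]
  tibble::tibble(
    n_conditions = nrow(def),
    min_replicates = min(def$n), max_replicates = max(def$n),
    peak_delay_h = peak$delay_h, peak_duration_h = peak$duration_h,
    peak_mean = peak$mean
  )
}

#' @export
print.colony_image <- function(x, ...) {
  cat(sprintf(
    "<colony_image> %d channel(s) [%s], %d x %d px at %.3g um/px\n",
    length(x$channels), paste(names(x$channels), collapse = ", "),
    nrow(x$channels[[1]]), ncol(x$channels[[1]]), x$pixel_size_um))
  invisible(x)
}

#' @export
print.density_model <- function(x, ...) {
  cat(sprintf(
    "<density_model> rho(t) = %g * 2^(t / %g h) cells/mm^2\n",
    x$rho0, x$doubling_time))
  invisible(x)
}
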