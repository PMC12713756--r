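#' Assign cell territories around nucleus seeds
#'
#' Partitions the image plane into per-cell territories by nearest nucleus
#' centroid, bounded by a maximum radius from the seed — the cell extent
#' needed to define a "membrane" band when no membrane marker is imaged.
#' No pixel has two owners, and pixels farther than `max_radius` from every
#' seed stay background.
#'
#' @param labels Integer nucleus label matrix from [detect_nuclei()].
#' @param max_radius Territory radius bound, micrometres (default 12).
#' @param pixel_size Micrometres per pixel (defaults to the label
#'   attribute).
#' @return Integer territory label matrix (same labels as the nuclei).
#' @export
cell_territories <- function(labels, max_radius = 12,
                             pixel_size = attr(labels, "pixel_size_um")) {
  stopifnot(is.matrix(labels))
  if (is.null(pixel_size)) pixel_size <- 0.65
  check_number(max_radius, "max_radius", lower = 0, allow_zero = FALSE)
  out <- matrix(0L, nrow(labels), ncol(labels))
  ids <- sort(unique(labels[labels > 0L]))
  if (!length(ids)) return(structure(out, pixel_size_um = pixel_size))
  best <- matrix(Inf, nrow(labels), ncol(labels))
  sel <- labels > 0L
  f <- factor(labels[sel], levels = ids)
  cx <- as.numeric(tapply(row(labels)[sel], f, mean))
  cy <- as.numeric(tapply(col(labels)[sel], f, mean))
  r_px <- max_radius / pixel_size
  for (k in seq_along(ids)) {
    ix <- max(1L, floor(cx[k] - r_px)):min(nrow(labels), ceiling(cx[k] + r_px))
    iy <- max(1L, floor(cy[k] - r_px)):min(ncol(labels), ceiling(cy[k] + r_px))
    d2 <- outer((ix - cx[k])^2, (iy - cy[k])^2, `+`)
    sub_best <- best[ix, iy, drop = FALSE]
    sub_out <- out[ix, iy, drop = FALSE]
    upd <- d2 <= r_px^2 & d2 < sub_best
    sub_best[upd] <- d2[upd]
    sub_out[upd] <- ids[k]
    best[ix, iy] <- sub_best
    out[ix, iy] <- sub_out
  }
  structure(out, pixel_size_um = pixel_size)
}

#' Non-membrane beta-catenin per cell
#'
#' Separates the signaling-active, non-membrane beta-catenin pool from the
#' membrane-bound pool by excluding a boundary band of `band_width`
#' micrometres along each territory's border (any border: neighbouring cell
#' or background). `nonmembrane_mean` is the mean intensity over the
#' territory interior. Cells whose band consumes the whole territory are
#' flagged degenerate with `NA` value.
#'
#' @param bcat_image Numeric matrix, the beta-catenin channel.
#' @param territories Territory label matrix from [cell_territories()].
#' @param band_width Membrane band width, micrometres (default 1.5).
#' @param pixel_size Micrometres per pixel.
#' @return A tibble `(cell_id, n_interior_px, n_membrane_px,
#'   nonmembrane_mean, membrane_mean, degenerate)`.
#' @export
nonmembrane_intensity <- function(bcat_image, territories, band_width = 1.5,
                                  pixel_size =
                                    attr(territories, "pixel_size_um")) {
  check_number(band_width, "band_width", lower = 0, allow_zero = FALSE)
  if (is.null(pixel_size)) pixel_size <- 0.65
  if (!identical(dim(bcat_image), dim(territories))) {
    stop_gastr("image and territories do not share geometry.",
               "geometry_error")
  }
  ids <- sort(unique(territories[territories > 0L]))
  if (!length(ids)) {
    return(tibble::tibble(cell_id = integer(), n_interior_px = integer(),
                          n_membrane_px = integer(),
                          nonmembrane_mean = numeric(),
                          membrane_mean = numeric(), degenerate = logical()))
  }
  # Border pixels: any 4-neighbour carries a different label (a neighbouring
  # cell or background). The membrane band is everything within band_width
  # of a border, measured by the Euclidean distance transform.
  n1 <- nrow(territories); n2 <- ncol(territories)
  shift <- function(m, dx, dy) {
    m[pmin(pmax(seq_len(n1) + dx, 1L), n1),
      pmin(pmax(seq_len(n2) + dy, 1L), n2), drop = FALSE]
  }
  border <- (territories != shift(territories, 1L, 0L)) |
    (territories != shift(territories, -1L, 0L)) |
    (territories != shift(territories, 0L, 1L)) |
    (territories != shift(territories, 0L, -1L))
  dist_px <- EBImage::imageData(
    EBImage::distmap(EBImage::as.Image(!border)))
  band_px <- band_width / pixel_size
  interior <- territories > 0L & dist_px > band_px
  membrane <- territories > 0L & !interior
  purrr::map_df(ids, function(id) {
    in_sel <- interior & territories == id
    mem_sel <- membrane & territories == id
    n_in <- sum(in_sel)
    tibble::tibble(
      cell_id = id,
      n_interior_px = n_in,
      n_membrane_px = sum(mem_sel),
      nonmembrane_mean = if (n_in) mean(bcat_image[in_sel]) else NA_real_,
      membrane_mean = if (sum(mem_sel)) mean(bcat_image[mem_sel])
                      else NA_real_,
      degenerate = n_in == 0L
    )
  })
}

#' Summarise a light-driven signaling time series per interval
#'
#' Splits the series into the scheduled ON intervals and the complementary
#' OFF intervals, reporting each interval's start and end values, signed
#' change, and a monotonicity verdict: `"increasing"` for ON intervals and
#' `"decreasing"` for OFF intervals when the change exceeds `tolerance` in
#' the expected direction, `"flat"` within tolerance, otherwise the
#' observed direction.
#'
#' @param series A `signaling_series` (from [simulate_bcat_series()] or a
#'   tibble with `t_h`, `value`).
#' @param schedule A [light_schedule()]; defaults to the series attribute.
#' @param tolerance Absolute change below which an interval counts as
#'   flat.
#' @return A tibble `(start_h, end_h, state, start_value, end_value,
#'   change, verdict)`.
#' @export
series_summary <- function(series, schedule = attr(series, "schedule"),
                           tolerance = 1e-6) {
  if (is.null(series) || !nrow(series)) {
    stop_gastr("empty series.", "insufficient_data")
  }
  if (is.null(schedule)) {
    stop_gastr("no light schedule available.", "parameter_error")
  }
  t0 <- min(series$t_h); t1 <- max(series$t_h)
  bounds <- sort(unique(c(t0, t1,
                          pmax(pmin(schedule$start_h, t1), t0),
                          pmax(pmin(schedule$end_h, t1), t0))))
  value_at <- function(tt) {
    series$value[which.min(abs(series$t_h - tt))]
  }
  purrr::map_df(seq_len(length(bounds) - 1), function(i) {
    a <- bounds[i]; b <- bounds[i + 1]
    mid <- (a + b) / 2
    on <- any(mid >= schedule$start_h & mid < schedule$end_h)
    v0 <- value_at(a); v1 <- value_at(b)
    ch <- v1 - v0
    verdict <- if (abs(ch) <= tolerance) "flat"
               else if (ch > 0) "increasing" else "decreasing"
    tibble::tibble(start_h = a, end_h = b, state = if (on) "on" else "off",
                   start_value = v0, end_value = v1, change = ch,
                   verdict = verdict)
  })
}
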