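#' Segmentation configuration
#'
#' All geometric parameters are in micrometres and converted by the pixel
#' size at run time, so one config works at any magnification.
#'
#' @param background_radius Radius of the morphological-opening structuring
#'   element used for background estimation, micrometres. Must exceed the
#'   nucleus radius.
#' @param dilation_radius Dilation applied to the thresholded DAPI mask
#'   before labelling, micrometres.
#' @param intensity_threshold `"otsu"` (parameter-free, the default) or
#'   `"fixed"`.
#' @param fixed_value Threshold intensity when `intensity_threshold =
#'   "fixed"`.
#' @param min_area,max_area Accepted nucleus area range, square micrometres.
#' @param min_circularity Minimum circularity `4*pi*A/P^2` (1 = perfect
#'   disc).
#' @return A `segmentation_config` list.
#' @export
segmentation_config <- function(background_radius = 20, dilation_radius = 1,
                                intensity_threshold = c("otsu", "fixed"),
                                fixed_value = NULL,
                                min_area = 30, max_area = 200,
                                min_circularity = 0.6) {
  intensity_threshold <- match.arg(intensity_threshold)
  check_number(background_radius, "background_radius", lower = 0,
               allow_zero = FALSE)
  check_number(dilation_radius, "dilation_radius", lower = 0)
  check_number(min_area, "min_area", lower = 0)
  check_number(max_area, "max_area", lower = 0)
  if (min_area >= max_area) {
    stop_gastr("`min_area` must be smaller than `max_area`.",
               "parameter_error")
  }
  check_number(min_circularity, "min_circularity", lower = 0, upper = 1)
  if (intensity_threshold == "fixed") {
    check_number(fixed_value, "fixed_value", lower = 0)
  }
  structure(
    list(background_radius = background_radius,
         dilation_radius = dilation_radius,
         intensity_threshold = intensity_threshold,
         fixed_value = fixed_value,
         min_area = min_area, max_area = max_area,
         min_circularity = min_circularity),
    class = "segmentation_config"
  )
}

#' Morphological-opening background subtraction
#'
#' Estimates the background as the greyscale morphological opening of the
#' image with a square structuring element of half-width
#' `background_radius` micrometres (which must be larger than a nucleus, so
#' nuclei are levelled out of the estimate) and subtracts it, clipping at
#' zero. On an already-flat background the operation is a no-op up to the
#' flat level, and it is invariant to adding a constant offset.
#'
#' @param image Numeric matrix (one channel).
#' @param background_radius Structuring-element radius, micrometres.
#' @param pixel_size Micrometres per pixel.
#' @return Numeric matrix of the same dimension.
#' @export
subtract_background <- function(image, background_radius = 20,
                                pixel_size = 0.65) {
  check_number(background_radius, "background_radius", lower = 0,
               allow_zero = FALSE)
  check_number(pixel_size, "pixel_size", lower = 0, allow_zero = FALSE)
  stopifnot(is.matrix(image), is.numeric(image))
  r <- max(1L, round(background_radius / pixel_size))
  bg <- grey_opening(image, r)
  pmax(image - bg, 0)
}

#' Detect nuclei in a background-subtracted DAPI image
#'
#' Threshold (Otsu by default) -> binary mask -> dilation -> distance-map
#' watershed to split touching nuclei -> filter components by area and
#' circularity. Returns an integer label matrix (background 0, labels
#' 1..n renumbered consecutively).
#'
#' @param dapi_image Background-subtracted DAPI channel, numeric matrix.
#' @param cfg A [segmentation_config()].
#' @param pixel_size Micrometres per pixel.
#' @return Integer label matrix with attribute `pixel_size_um`.
#' @export
detect_nuclei <- function(dapi_image, cfg = segmentation_config(),
                          pixel_size = 0.65) {
  stopifnot(inherits(cfg, "segmentation_config"), is.matrix(dapi_image))
  mx <- max(dapi_image)
  if (mx <= 0) {
    lab <- matrix(0L, nrow(dapi_image), ncol(dapi_image))
    attr(lab, "pixel_size_um") <- pixel_size
    return(lab)
  }
  th <- if (cfg$intensity_threshold == "otsu") {
    EBImage::otsu(EBImage::as.Image(dapi_image / mx), range = c(0, 1)) * mx
  } else {
    cfg$fixed_value
  }
  mask <- dapi_image > th
  if (cfg$dilation_radius > 0) {
    mask <- EBImage::imageData(
      EBImage::dilate(EBImage::as.Image(mask),
                      um_brush(cfg$dilation_radius, pixel_size))) > 0
  }
  if (!any(mask)) {
    lab <- matrix(0L, nrow(dapi_image), ncol(dapi_image))
    attr(lab, "pixel_size_um") <- pixel_size
    return(lab)
  }
  dm <- EBImage::distmap(EBImage::as.Image(mask))
  labs <- EBImage::watershed(dm, tolerance = 1, ext = 1)
  shp <- EBImage::computeFeatures.shape(labs)
  area_um2 <- shp[, "s.area"] * pixel_size^2
  circ <- pmin(4 * pi * shp[, "s.area"] / pmax(shp[, "s.perimeter"], 1)^2, 1)
  bad <- which(area_um2 < cfg$min_area | area_um2 > cfg$max_area |
                 circ < cfg$min_circularity)
  if (length(bad)) {
    labs <- EBImage::rmObjects(labs, bad, reenumerate = TRUE)
  }
  lab <- EBImage::imageData(labs)
  storage.mode(lab) <- "integer"
  attr(lab, "pixel_size_um") <- pixel_size
  lab
}

#' Measure per-nucleus morphology and marker intensities
#'
#' One record per label: centroid (micrometres, colony-image origin at the
#' image centre), area, circularity, and the arithmetic mean of each
#' channel's pixels under the label.
#'
#' @param labels Integer label matrix from [detect_nuclei()].
#' @param channel_images Named list of numeric matrices sharing the label
#'   geometry.
#' @param pixel_size Micrometres per pixel (defaults to the label
#'   attribute).
#' @return A tibble: `nucleus_id`, `x_um`, `y_um`, `area_um2`,
#'   `circularity`, one column per channel.
#' @export
measure_markers <- function(labels, channel_images,
                            pixel_size = attr(labels, "pixel_size_um")) {
  stopifnot(is.matrix(labels))
  if (is.null(pixel_size)) pixel_size <- 0.65
  if (is.null(names(channel_images)) || anyDuplicated(names(channel_images))) {
    stop_gastr("`channel_images` must be a uniquely named list.",
               "parameter_error")
  }
  for (ch in names(channel_images)) {
    if (!identical(dim(channel_images[[ch]]), dim(labels))) {
      stop_gastr(sprintf("channel '%s' does not share the label geometry.",
                         ch), "geometry_error")
    }
  }
  ids <- sort(unique(labels[labels > 0L]))
  if (!length(ids)) {
    out <- tibble::tibble(nucleus_id = integer(), x_um = numeric(),
                          y_um = numeric(), area_um2 = numeric(),
                          circularity = numeric())
    for (ch in names(channel_images)) out[[ch]] <- numeric()
    return(out)
  }
  sel <- labels > 0L
  lab_v <- labels[sel]
  f <- factor(lab_v, levels = ids)
  n_px <- dim(labels)
  xs <- row(labels)[sel]
  ys <- col(labels)[sel]
  area_px <- as.numeric(table(f))
  cx <- as.numeric(tapply(xs, f, mean))
  cy <- as.numeric(tapply(ys, f, mean))
  shp <- EBImage::computeFeatures.shape(labels)
  circ <- pmin(4 * pi * shp[, "s.area"] / pmax(shp[, "s.perimeter"], 1)^2, 1)
  out <- tibble::tibble(
    nucleus_id = seq_along(ids),
    x_um = px_to_um(cx, n_px[1], pixel_size),
    y_um = px_to_um(cy, n_px[2], pixel_size),
    area_um2 = area_px * pixel_size^2,
    circularity = as.numeric(circ[as.character(ids), drop = TRUE])
  )
  for (ch in names(channel_images)) {
    out[[ch]] <- as.numeric(tapply(channel_images[[ch]][sel], f, mean))
  }
  out
}

#' Segment a rendered colony image end to end
#'
#' Convenience wrapper: background-subtract every channel, detect nuclei on
#' DAPI, and measure all channels under the nucleus labels.
#'
#' @param image A `colony_image` (from [render_colony()] or
#'   [read_colony_tiff()]).
#' @param cfg A [segmentation_config()].
#' @param dapi_channel Name of the nuclear channel (default `"DAPI"`).
#' @return The nucleus table of [measure_markers()].
#' @export
segment_colony <- function(image, cfg = segmentation_config(),
                           dapi_channel = "DAPI") {
  stopifnot(inherits(image, "colony_image"))
  if (!dapi_channel %in% names(image$channels)) {
    stop_gastr(sprintf("channel '%s' not present in the image.",
                       dapi_channel), "parameter_error")
  }
  px <- image$pixel_size_um
  sub <- lapply(image$channels, subtract_background,
                background_radius = cfg$background_radius, pixel_size = px)
  labels <- detect_nuclei(sub[[dapi_channel]], cfg, pixel_size = px)
  measure_markers(labels, sub, pixel_size = px)
}
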