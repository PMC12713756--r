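#' Edge/centre region conventions for the Pattern Fidelity Index
#'
#' Two edge-region dialects are in use, matching how screen colonies differ
#' from BMP4-patterned ones: uniformly illuminated screen colonies push the
#' BRA ring against the colony edge, so their edge band is 10-40 um from the
#' edge (`"screen"`); a normally BMP4-patterned colony carries its BRA ring
#' deeper, 50-80 um (`"target"`). The centre region is 210-240 um in both.
#' All regions are expressed in micrometres from the colony edge; bin-index
#' labels are ambiguous and never used.
#'
#' @param dialect `"screen"` or `"target"`.
#' @return A list with `edge` and `center` numeric `(lo, hi)` vectors (um
#'   from edge) and the dialect name.
#' @export
pfi_regions <- function(dialect = c("screen", "target")) {
  dialect <- match.arg(dialect)
  edge <- switch(dialect, screen = c(10, 40), target = c(50, 80))
  list(edge = edge, center = c(210, 240), dialect = dialect)
}

#' Mean profile intensity over a micrometre region
#'
#' Averages the bin means of all nonempty bins whose interval lies within
#' `[lo, hi)`. Unweighted across bins by default (each bin value counts
#' once); set `weighted = TRUE` to weight by per-bin nucleus counts.
#'
#' @param profile A [bin_radial()] profile.
#' @param region Numeric `(lo, hi)` in micrometres from the edge, `lo < hi`.
#' @param weighted Weight bin means by `n`?
#' @return A single intensity (arbitrary units).
#' @export
region_mean <- function(profile, region, weighted = FALSE) {
  if (length(region) != 2 || region[1] >= region[2]) {
    stop_gastr("`region` must be (lo, hi) with lo < hi.", "parameter_error")
  }
  sel <- profile$bin_lo_um >= region[1] & profile$bin_hi_um <= region[2] &
    profile$n > 0 & !is.na(profile$mean)
  if (!any(sel)) {
    stop_gastr("no nonempty profile bin lies within the region.",
               "empty_region")
  }
  if (weighted) {
    sum(profile$mean[sel] * profile$n[sel]) / sum(profile$n[sel])
  } else {
    mean(profile$mean[sel])
  }
}

#' Pattern Fidelity Index
#'
#' `PFI = (Edge - Center) / (Edge + Center)`, a bounded index in `[-1, 1]`:
#' 1 when all signal sits in the edge band, -1 when it all sits in the
#' centre, 0 when the two regions are equally bright. Undefined (NA) when
#' both region means are zero.
#'
#' @param edge,center Non-negative region mean intensities.
#' @return The PFI (dimensionless), vectorised over inputs.
#' @export
compute_pfi <- function(edge, center) {
  if (any(edge < 0, na.rm = TRUE) || any(center < 0, na.rm = TRUE)) {
    stop_gastr("region means must be non-negative.", "domain_error")
  }
  out <- (edge - center) / (edge + center)
  out[(edge + center) == 0] <- NA_real_
  out
}

#' Classify a PFI value into a pattern phenotype
#'
#' Thresholds follow the published calibration: BMP4-patterned colonies
#' exceed 0.32 ("high"), 0.1-0.32 is "low" fidelity, values within 0.1 of
#' zero are "uniform", and values below -0.1 are "inverted". Boundaries are
#' closed on the uniform side and 0.32 maps to "low", making the partition
#' total; `NA` maps to "undefined".
#'
#' @param pfi Numeric vector of PFI values (or `NA`).
#' @return Character vector: `"inverted"`, `"uniform"`, `"low"`, `"high"`,
#'   or `"undefined"`.
#' @export
classify_pfi <- function(pfi) {
  dplyr::case_when(
    is.na(pfi) ~ "undefined",
    pfi < -0.1 ~ "inverted",
    pfi <= 0.1 ~ "uniform",
    pfi <= 0.32 ~ "low",
    TRUE ~ "high"
  )
}

#' PFI of a radial profile
#'
#' Composes [region_mean()] on the edge and centre regions, [compute_pfi()]
#' and [classify_pfi()], recording which edge-region dialect was used.
#'
#' @param profile A [bin_radial()] profile.
#' @param dialect `"screen"` (edge 10-40 um) or `"target"` (edge 50-80 um);
#'   see [pfi_regions()].
#' @param edge_region,center_region Optional explicit `(lo, hi)` regions in
#'   micrometres overriding the dialect.
#' @param weighted Passed to [region_mean()].
#' @return A one-row tibble
#'   `(edge_mean, center_mean, pfi, phenotype, dialect)`.
#' @export
pfi_from_profile <- function(profile, dialect = c("screen", "target"),
                             edge_region = NULL, center_region = NULL,
                             weighted = FALSE) {
  reg <- pfi_regions(match.arg(dialect))
  edge_region <- edge_region %||% reg$edge
  center_region <- center_region %||% reg$center
  e <- region_mean(profile, edge_region, weighted = weighted)
  c0 <- region_mean(profile, center_region, weighted = weighted)
  pfi <- compute_pfi(e, c0)
  tibble::tibble(edge_mean = e, center_mean = c0, pfi = pfi,
                 phenotype = classify_pfi(pfi), dialect = reg$dialect)
}

#' Annulus (integrated-density) PFI computed directly from an image
#'
#' The manual variant used when no nuclear channel is available. The edge
#' value is the mean intensity over the annulus between the colony disc
#' shrunk by `edge_offsets[1]` and by `edge_offsets[2]` micrometres,
#' computed from integrated densities: the larger shrunk disc's integrated
#' density minus the smaller one's, divided by the annulus area (the
#' minuend/subtrahend order is fixed so the result is the annulus mean).
#' The centre value is the mean over the central region. Both feed
#' [compute_pfi()] / [classify_pfi()].
#'
#' @param image Numeric matrix (one marker channel).
#' @param disc A [fit_disc()] result, micrometre frame with origin at the
#'   image centre.
#' @param pixel_size Micrometres per pixel.
#' @param edge_offsets Numeric `(outer, inner)` offsets from the colony
#'   edge bounding the annulus, micrometres (default `c(51, 80)`).
#' @param center_region `(lo, hi)` centre region, micrometres from edge.
#' @return A one-row tibble like [pfi_from_profile()], dialect
#'   `"annulus"`.
#' @export
annulus_pfi <- function(image, disc, pixel_size = 0.65,
                        edge_offsets = c(51, 80),
                        center_region = c(210, 240)) {
  stopifnot(inherits(disc, "colony_disc"), is.matrix(image))
  if (any(edge_offsets >= disc$radius_um)) {
    stop_gastr("edge offsets must be smaller than the colony radius.",
               "geometry_error")
  }
  n_px <- dim(image)
  x_um <- px_to_um(seq_len(n_px[1]), n_px[1], pixel_size)
  y_um <- px_to_um(seq_len(n_px[2]), n_px[2], pixel_size)
  dist <- sqrt(outer((x_um - disc$cx_um)^2, (y_um - disc$cy_um)^2, `+`))
  depth <- disc$radius_um - dist
  off <- sort(edge_offsets)
  big <- depth >= off[1]           # disc shrunk by the smaller offset
  small <- depth >= off[2]         # disc shrunk by the larger offset
  n_ann <- sum(big) - sum(small)
  if (n_ann <= 0) {
    stop_gastr("annulus contains no pixels at this resolution.",
               "geometry_error")
  }
  edge_mean <- (sum(image[big]) - sum(image[small])) / n_ann
  ctr <- depth >= center_region[1] & depth < center_region[2]
  if (!any(ctr)) {
    stop_gastr("centre region contains no pixels.", "geometry_error")
  }
  center_mean <- mean(image[ctr])
  pfi <- compute_pfi(max(edge_mean, 0), max(center_mean, 0))
  tibble::tibble(edge_mean = edge_mean, center_mean = center_mean,
                 pfi = pfi, phenotype = classify_pfi(pfi),
                 dialect = "annulus")
}
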