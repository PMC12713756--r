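#' Write a colony image as a multi-page TIFF with a ground-truth sidecar
#'
#' One 32-bit page per channel. TIFF float pages are stored scaled by
#' `1/scale` into `[0, 1]`; [read_colony_tiff()] applies the inverse.
#' Channel names and the scale travel in a sidecar `.yml`; the nucleus
#' table, if given, is written as `<path>.csv` (`x_um`, `y_um`, one column
#' per channel).
#'
#' @param image A `colony_image`.
#' @param path Output TIFF path.
#' @param table Optional nucleus ground-truth table to write alongside.
#' @param scale Intensity scale factor (default 65535).
#' @return `path`, invisibly.
#' @export
write_colony_tiff <- function(image, path, table = NULL, scale = 65535) {
  stopifnot(inherits(image, "colony_image"))
  pages <- unname(lapply(image$channels,
                         function(m) pmax(pmin(m / scale, 1), 0)))
  tiff::writeTIFF(pages, path, bits.per.sample = 32, reduce = FALSE)
  meta <- list(channels = names(image$channels), scale = scale,
               pixel_size_um = image$pixel_size_um,
               extent_um = image$extent_um,
               radius_um = image$radius_um %||% NA)
  yaml::write_yaml(meta, paste0(path, ".yml"))
  if (!is.null(table)) {
    utils::write.csv(table, paste0(path, ".csv"), row.names = FALSE)
  }
  invisible(path)
}

#' Read a colony image written by [write_colony_tiff()]
#'
#' @param path TIFF path (its `.yml` sidecar must be present).
#' @return A `colony_image`.
#' @export
read_colony_tiff <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".yml"))
  pages <- tiff::readTIFF(path, all = TRUE)
  chans <- lapply(pages, function(p) p * meta$scale)
  names(chans) <- meta$channels
  structure(
    list(channels = chans, pixel_size_um = meta$pixel_size_um,
         extent_um = meta$extent_um,
         radius_um = if (is.na(meta$radius_um)) NULL else meta$radius_um),
    class = "colony_image"
  )
}

#' Write a tibble as CSV with a provenance header block
#'
#' Prepends `#`-comment lines recording the config hash, seed and package
#' version, so every artifact of a pipeline run is traceable; read back
#' with [read_stamped_csv()].
#'
#' @param x A data frame.
#' @param path Output path.
#' @param config_hash,seed Provenance fields (may be `NA`).
#' @return `path`, invisibly.
#' @export
write_stamped_csv <- function(x, path, config_hash = NA, seed = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# config_hash: %s", config_hash),
    sprintf("# seed: %s", seed),
    sprintf("# package: gastruloidr %s",
            as.character(utils::packageVersion("gastruloidr")))
  ), con)
  utils::write.csv(x, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_stamped_csv
#' @export
read_stamped_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, comment.char = "#"))
}
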