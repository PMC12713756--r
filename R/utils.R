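# Internal helpers shared across modules.

# Stop with a classed condition so tests can assert on error class.
stop_gastr <- function(msg, class) {
  rlang::abort(msg, class = paste0("gastruloidr_", class))
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_zero = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_gastr(sprintf("`%s` must be a single finite number.", name),
               "parameter_error")
  }
  if (x < lower || x > upper || (!allow_zero && x == 0)) {
    stop_gastr(sprintf("`%s` = %g is outside its valid range.", name, x),
               "parameter_error")
  }
  invisible(x)
}

# Greyscale running min/max filter along one matrix dimension with
# edge-replicate boundary handling (window half-width r pixels).
filter_1d <- function(m, r, op, margin) {
  out <- m
  n <- dim(m)[margin]
  for (k in seq_len(r)) {
    up <- pmin(seq_len(n) + k, n)
    dn <- pmax(seq_len(n) - k, 1L)
    if (margin == 1L) {
      out <- op(out, m[up, , drop = FALSE], m[dn, , drop = FALSE])
    } else {
      out <- op(out, m[, up, drop = FALSE], m[, dn, drop = FALSE])
    }
  }
  out
}

# Separable greyscale erosion/dilation with a (2r+1)^2 square window.
grey_erode <- function(m, r) filter_1d(filter_1d(m, r, pmin, 1L), r, pmin, 2L)
grey_dilate <- function(m, r) filter_1d(filter_1d(m, r, pmax, 1L), r, pmax, 2L)

# Greyscale opening: erosion then dilation; levels out structures smaller
# than the window while preserving the smooth background.
grey_opening <- function(m, r) grey_dilate(grey_erode(m, r), r)

# Odd-diameter disc brush for a radius given in micrometres.
um_brush <- function(radius_um, pixel_size_um) {
  r_px <- max(1L, round(radius_um / pixel_size_um))
  EBImage::makeBrush(2L * r_px + 1L, shape = "disc")
}

# Map matrix indices (dim 1 = x, dim 2 = y) to micrometre coordinates with
# the colony centre at (0, 0). Pixel i spans [(i-1)*px, i*px); its centre is
# at (i - 0.5)*px - half_extent.
px_to_um <- function(idx, n_px, pixel_size_um) {
  (idx - 0.5) * pixel_size_um - n_px * pixel_size_um / 2
}

um_to_px <- function(u, n_px, pixel_size_um) {
  (u + n_px * pixel_size_um / 2) / pixel_size_um + 0.5
}
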