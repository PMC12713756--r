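# Shared fixtures and oracles, all built in code.

# Greedy one-to-one matching of detected nuclei to ground truth; a match is
# a centroid pair within `tol` micrometres (one nucleus radius).
match_detections <- function(truth, det, tol = 5) {
  if (!nrow(det) || !nrow(truth)) return(c(recall = 0, precision = 0))
  d <- sqrt(outer(truth$x_um, det$x_um, `-`)^2 +
              outer(truth$y_um, det$y_um, `-`)^2)
  matched <- 0
  repeat {
    mn <- suppressWarnings(min(d))
    if (!is.finite(mn) || mn > tol) break
    m <- which(d == mn, arr.ind = TRUE)[1, ]
    matched <- matched + 1
    d[m[1], ] <- Inf
    d[, m[2]] <- Inf
  }
  c(recall = matched / nrow(truth), precision = matched / nrow(det))
}

# Colony spec for a generating phenotype, in the geometry each PFI dialect
# expects: screen-context rings sit against the colony edge (peak 25 um in),
# BMP4-like rings sit in the 50-80 um target band (peak 65 um in).
phenotype_spec <- function(kind, seed, dialect = "screen", density = 1500) {
  depth <- if (dialect == "screen") 25 else 65
  sigma <- if (dialect == "screen") 25 else 15
  colony_spec(
    density = density,
    channels = list(
      DAPI = pattern_params("uniform", amplitude = 100, background = 0,
                            noise_sd = 5),
      BRA = pattern_params(kind, ring_center_depth = depth,
                           ring_sigma = sigma)
    ),
    seed = seed
  )
}

# The pattern class a generating phenotype should classify as; an absent
# field is flat, so it reads as uniform.
expected_class <- function(kind) {
  c(ring = "high", inverted = "inverted", uniform = "uniform",
    absent = "uniform")[[kind]]
}

# PFI of a ground-truth point table (no imaging), for truth-level checks.
truth_pfi <- function(tbl, radius = 250, dialect = "screen") {
  disc <- fit_disc(tbl, known_radius = radius)
  pfi_from_profile(bin_radial(edge_depth(tbl, disc), "BRA", disc = disc),
                   dialect = dialect)
}

# Brute-force radial binning oracle: group nuclei by floor(depth / w) and
# average, independent of the bin_radial implementation.
oracle_bin <- function(depth, value, w, radius) {
  n_bins <- ceiling(radius / w)
  keep <- depth >= 0 & depth <= radius
  depth <- depth[keep]; value <- value[keep]
  idx <- pmin(floor(depth / w), n_bins - 1) + 1
  out <- data.frame(bin = seq_len(n_bins), mean = NA_real_, n = 0L)
  for (b in seq_len(n_bins)) {
    v <- value[idx == b]
    out$n[b] <- length(v)
    if (length(v)) out$mean[b] <- sum(v) / length(v)
  }
  out
}
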