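#' Fit the colony disc under a nucleus table
#'
#' With a known radius (the default 250 um: micropatterned geometry is
#' fixed by the stamp) the centre is the centroid of the nucleus positions.
#' With `known_radius = NULL` the minimal enclosing circle of the centroids
#' is computed instead (Welzl's algorithm).
#'
#' @param table Nucleus table with `x_um`, `y_um` (at least 3 rows).
#' @param known_radius Colony radius in micrometres, or `NULL` to estimate.
#' @return A `colony_disc`: one-row tibble `(cx_um, cy_um, radius_um)`.
#' @export
fit_disc <- function(table, known_radius = 250) {
  if (nrow(table) < 3) {
    stop_gastr("at least 3 nuclei are needed to fit the colony disc.",
               "insufficient_data")
  }
  if (!is.null(known_radius)) {
    check_number(known_radius, "known_radius", lower = 0, allow_zero = FALSE)
    disc <- tibble::tibble(cx_um = mean(table$x_um),
                           cy_um = mean(table$y_um),
                           radius_um = known_radius)
  } else {
    mec <- min_enclosing_circle(cbind(table$x_um, table$y_um))
    disc <- tibble::tibble(cx_um = mec$cx, cy_um = mec$cy,
                           radius_um = mec$r)
  }
  structure(disc, class = c("colony_disc", class(tibble::tibble())))
}

# Welzl's minimal enclosing circle (iterative move-to-front variant).
min_enclosing_circle <- function(pts) {
  n <- nrow(pts)
  circ_2 <- function(a, b) {
    c(cx = (a[1] + b[1]) / 2, cy = (a[2] + b[2]) / 2,
      r = sqrt(sum((a - b)^2)) / 2)
  }
  circ_3 <- function(a, b, c3) {
    ax <- a[1]; ay <- a[2]; bx <- b[1]; by <- b[2]; cx <- c3[1]; cy <- c3[2]
    d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
    if (abs(d) < 1e-12) return(NULL)  # collinear
    ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
             (cx^2 + cy^2) * (ay - by)) / d
    uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
             (cx^2 + cy^2) * (bx - ax)) / d
    c(cx = ux, cy = uy, r = sqrt((ax - ux)^2 + (ay - uy)^2))
  }
  inside <- function(circ, p, tol = 1e-9) {
    sqrt((p[1] - circ[1])^2 + (p[2] - circ[2])^2) <= circ[3] + tol
  }
  trivial <- function(boundary) {
    k <- nrow(boundary)
    if (k == 0) return(c(cx = 0, cy = 0, r = 0))
    if (k == 1) return(c(cx = boundary[1, 1], cy = boundary[1, 2], r = 0))
    if (k == 2) return(circ_2(boundary[1, ], boundary[2, ]))
    # try pairs first (the 3-point circle may be degenerate)
    for (i in 1:2) for (j in (i + 1):3) {
      cc <- circ_2(boundary[i, ], boundary[j, ])
      if (all(apply(boundary, 1, function(p) inside(cc, p)))) return(cc)
    }
    circ_3(boundary[1, ], boundary[2, ], boundary[3, ])
  }
  welzl <- function(pts, boundary) {
    if (nrow(pts) == 0 || nrow(boundary) == 3) return(trivial(boundary))
    p <- pts[nrow(pts), ]
    cc <- welzl(pts[-nrow(pts), , drop = FALSE], boundary)
    if (!is.null(cc) && inside(cc, p)) return(cc)
    welzl(pts[-nrow(pts), , drop = FALSE],
          rbind(boundary, p))
  }
  cc <- welzl(pts, matrix(numeric(), 0, 2))
  list(cx = unname(cc[1]), cy = unname(cc[2]), r = unname(cc[3]))
}

#' Add distance-from-edge depth to a nucleus table
#'
#' `depth_um = radius - distance(nucleus, centre)`. Nuclei outside the disc
#' (negative depth, typically segmentation spillover) are flagged
#' `in_disc = FALSE` and excluded by downstream binning.
#'
#' @param table Nucleus table with `x_um`, `y_um`.
#' @param disc A [fit_disc()] result.
#' @return The table with `depth_um` and `in_disc` columns (replacing any
#'   existing ones).
#' @export
edge_depth <- function(table, disc) {
  stopifnot(inherits(disc, "colony_disc"))
  table |>
    dplyr::mutate(
      depth_um = disc$radius_um -
        sqrt((.data$x_um - disc$cx_um)^2 + (.data$y_um - disc$cy_um)^2),
      in_disc = .data$depth_um >= 0
    )
}

#' Bin a nucleus table into a radial intensity profile
#'
#' Bins are half-open `[k*w, (k+1)*w)` micrometres from the colony edge
#' (a nucleus exactly at the centre falls in the innermost bin). The per-bin
#' mean is the arithmetic mean of per-nucleus intensities; empty bins carry
#' `NA` mean and `n = 0`. The per-bin counts always sum to the number of
#' in-disc nuclei.
#'
#' @param table Nucleus table with a `depth_um` column (see [edge_depth()]).
#' @param channel Channel column name, e.g. `"BRA"`.
#' @param bin_width Bin width, micrometres (default 10).
#' @param disc The [fit_disc()] result (sets the profile extent).
#' @return A `radial_profile` tibble:
#'   `(channel, bin_lo_um, bin_hi_um, mean, sem, n)`.
#' @export
bin_radial <- function(table, channel, bin_width = 10, disc = NULL) {
  check_number(bin_width, "bin_width", lower = 0, allow_zero = FALSE)
  if (!"depth_um" %in% names(table)) {
    stop_gastr("`table` lacks a `depth_um` column; run edge_depth() first.",
               "parameter_error")
  }
  if (!channel %in% names(table)) {
    stop_gastr(sprintf("channel '%s' not present in the table.", channel),
               "parameter_error")
  }
  radius <- if (!is.null(disc)) disc$radius_um else 250
  n_bins <- ceiling(radius / bin_width)
  tbl <- table
  if ("in_disc" %in% names(tbl)) tbl <- dplyr::filter(tbl, .data$in_disc)
  tbl <- dplyr::filter(tbl, .data$depth_um >= 0)
  idx <- pmin(floor(tbl$depth_um / bin_width), n_bins - 1L) + 1L
  v <- tbl[[channel]]
  mean_b <- rep(NA_real_, n_bins)
  sem_b <- rep(NA_real_, n_bins)
  n_b <- tabulate(idx, nbins = n_bins)
  if (length(v)) {
    f <- factor(idx, levels = seq_len(n_bins))
    mean_b <- as.numeric(tapply(v, f, mean))
    sem_b <- as.numeric(tapply(v, f, function(x) {
      if (length(x) > 1) sd(x) / sqrt(length(x)) else NA_real_
    }))
  }
  structure(
    tibble::tibble(
      channel = channel,
      bin_lo_um = (seq_len(n_bins) - 1) * bin_width,
      bin_hi_um = seq_len(n_bins) * bin_width,
      mean = mean_b, sem = sem_b, n = n_b
    ),
    radius_um = radius, bin_width_um = bin_width,
    class = c("radial_profile", class(tibble::tibble()))
  )
}

#' Average radial profiles across replicate colonies
#'
#' Replicates are averaged unweighted (each colony is one experimental
#' unit): per-bin mean of replicate means, SEM over replicates, counts
#' summed. Bins empty in a replicate are dropped from that bin's average.
#'
#' @param profiles List of [bin_radial()] profiles with identical bins.
#' @return A `radial_profile` tibble.
#' @export
average_profiles <- function(profiles) {
  if (!length(profiles)) {
    stop_gastr("need at least one profile.", "insufficient_data")
  }
  ref <- profiles[[1]]
  for (p in profiles[-1]) {
    if (!identical(p$bin_lo_um, ref$bin_lo_um) ||
        !identical(p$bin_hi_um, ref$bin_hi_um) ||
        !identical(p$channel[1], ref$channel[1])) {
      stop_gastr("profiles have mismatched bins or channels.",
                 "incompatibility_error")
    }
  }
  means <- vapply(profiles, function(p) p$mean, numeric(nrow(ref)))
  means <- matrix(means, nrow = nrow(ref))
  ns <- vapply(profiles, function(p) p$n, numeric(nrow(ref)))
  ns <- matrix(ns, nrow = nrow(ref))
  k <- rowSums(!is.na(means))
  avg <- rowMeans(means, na.rm = TRUE)
  avg[k == 0] <- NA_real_
  sem <- apply(means, 1, function(x) {
    x <- x[!is.na(x)]
    if (length(x) > 1) sd(x) / sqrt(length(x)) else NA_real_
  })
  structure(
    tibble::tibble(channel = ref$channel, bin_lo_um = ref$bin_lo_um,
                   bin_hi_um = ref$bin_hi_um, mean = avg, sem = sem,
                   n = as.integer(rowSums(ns))),
    radius_um = attr(ref, "radius_um"),
    bin_width_um = attr(ref, "bin_width_um"),
    class = class(ref)
  )
}

#' Pixelwise colony-average image
#'
#' Translates each image so the fitted disc centres coincide (integer-pixel
#' shifts), crops to the common extent, and averages pixelwise — the
#' "colony average over replicates" representation.
#'
#' @param images List of numeric matrices (one channel each).
#' @param discs List of [fit_disc()] results, one per image, in the same
#'   micrometre frame as the image (origin at the image centre).
#' @param pixel_size Micrometres per pixel.
#' @return A numeric matrix.
#' @export
average_colony_image <- function(images, discs, pixel_size = 0.65) {
  if (!length(images) || length(images) != length(discs)) {
    stop_gastr("`images` and `discs` must be nonempty and equal length.",
               "parameter_error")
  }
  shifts <- lapply(discs, function(d) {
    c(round(d$cx_um / pixel_size), round(d$cy_um / pixel_size))
  })
  dims <- vapply(images, dim, integer(2))
  # After shifting image i by -shift_i, the usable half-extent around the
  # common centre is limited by the smallest margin over all images.
  half <- min(vapply(seq_along(images), function(i) {
    min(floor(dims[1, i] / 2) - abs(shifts[[i]][1]),
        floor(dims[2, i] / 2) - abs(shifts[[i]][2]))
  }, numeric(1)))
  if (half < 1) {
    stop_gastr("images do not overlap after registration.", "geometry_error")
  }
  acc <- matrix(0, 2 * half, 2 * half)
  for (i in seq_along(images)) {
    ctr <- floor(dims[, i] / 2) + shifts[[i]]
    acc <- acc + images[[i]][(ctr[1] - half + 1):(ctr[1] + half),
                             (ctr[2] - half + 1):(ctr[2] + half)]
  }
  acc / length(images)
}
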