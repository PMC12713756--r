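#' Parametric radial intensity field for a synthetic colony channel
#'
#' Describes how a marker's mean intensity varies with depth (distance from
#' the colony edge). Four kinds of field cover the pattern phenotypes seen in
#' micropatterned 2D gastruloids:
#'
#' * `"ring"` — a Gaussian bump centred `ring_center_depth` micrometres in
#'   from the edge, the canonical outer mesoderm (BRA) band;
#' * `"inverted"` — the same Gaussian with its peak at the colony centre
#'   (depth = colony radius), i.e. mesoderm in the middle, the inverted
#'   phenotype;
#' * `"uniform"` — a flat field at `background + amplitude`, the
#'   evenly-distributed phenotype;
#' * `"absent"` — flat at `background` only (no differentiation).
#'
#' @param pattern_kind One of `"ring"`, `"inverted"`, `"uniform"`, `"absent"`.
#' @param ring_center_depth Depth of the ring peak, micrometres from the
#'   colony edge. Default 75, in the middle of the 50-100 um band where the
#'   BRA ring of a BMP4-patterned colony sits.
#' @param ring_sigma Gaussian width of the ring, micrometres.
#' @param amplitude Peak intensity above background, arbitrary units, >= 0.
#' @param background Baseline intensity, arbitrary units, >= 0.
#' @param noise_sd Per-nucleus Gaussian intensity noise, arbitrary units.
#' @return A `pattern_params` list.
#' @seealso [radial_field()], [colony_spec()]
#' @export
pattern_params <- function(pattern_kind = c("ring", "inverted", "uniform",
                                            "absent"),
                           ring_center_depth = 75, ring_sigma = 25,
                           amplitude = 100, background = 10, noise_sd = 10) {
  pattern_kind <- match.arg(pattern_kind)
  check_number(ring_center_depth, "ring_center_depth", lower = 0)
  check_number(ring_sigma, "ring_sigma", lower = 0, allow_zero = FALSE)
  check_number(amplitude, "amplitude", lower = 0)
  check_number(background, "background", lower = 0)
  check_number(noise_sd, "noise_sd", lower = 0)
  structure(
    list(pattern_kind = pattern_kind, ring_center_depth = ring_center_depth,
         ring_sigma = ring_sigma, amplitude = amplitude,
         background = background, noise_sd = noise_sd),
    class = "pattern_params"
  )
}

#' Evaluate a radial field at given depths
#'
#' Deterministic, noise-free field value as a function of depth from the
#' colony edge. The inverted field is the ring formula with its centre moved
#' to the colony centre, so `radius` must be supplied for that kind.
#'
#' @param params A [pattern_params()] object.
#' @param depth Numeric vector of depths, micrometres from the colony edge.
#' @param radius Colony radius in micrometres (default 250, a 500 um disc).
#' @return Numeric vector of intensities (arbitrary units).
#' @examples
#' p <- pattern_params("ring", ring_center_depth = 25, ring_sigma = 10,
#'                     amplitude = 100, background = 0)
#' radial_field(p, c(25, 35), radius = 250)
#' @export
radial_field <- function(params, depth, radius = 250) {
  stopifnot(inherits(params, "pattern_params"))
  check_number(radius, "radius", lower = 0, allow_zero = FALSE)
  if (any(!is.finite(depth)) || any(depth < 0) || any(depth > radius)) {
    stop_gastr("`depth` must lie within [0, radius].", "range_error")
  }
  if (params$ring_center_depth > radius) {
    stop_gastr("`ring_center_depth` exceeds the colony radius.", "range_error")
  }
  centre <- switch(params$pattern_kind,
                   ring = params$ring_center_depth,
                   inverted = radius,
                   NA_real_)
  switch(params$pattern_kind,
    ring = ,
    inverted = params$background + params$amplitude *
      exp(-(depth - centre)^2 / (2 * params$ring_sigma^2)),
    uniform = rep(params$background + params$amplitude, length(depth)),
    absent = rep(params$background, length(depth))
  )
}

#' Specification of one synthetic colony
#'
#' @param radius Colony radius, micrometres. Default 250 (500 um
#'   micropatterned disc).
#' @param density Target nucleus density, cells/mm^2. Default 1500, the
#'   standard seeding density.
#' @param nucleus_radius Nucleus radius, micrometres.
#' @param channels Named list of [pattern_params()], one per marker channel.
#'   The default carries a flat DAPI channel and a ring-patterned BRA channel.
#' @param seed Integer seed; colonies are reproducible for a fixed seed.
#' @param min_separation Hard-core minimum centre-to-centre distance in
#'   micrometres (default one nucleus diameter); set to 0 to disable.
#' @return A `colony_spec` list.
#' @export
colony_spec <- function(radius = 250, density = 1500, nucleus_radius = 5,
                        channels = list(
                          DAPI = pattern_params("uniform", amplitude = 100,
                                                background = 0, noise_sd = 5),
                          BRA = pattern_params("ring")
                        ),
                        seed = 1L,
                        min_separation = 2 * nucleus_radius) {
  check_number(radius, "radius", lower = 0, allow_zero = FALSE)
  check_number(density, "density", lower = 0)
  check_number(nucleus_radius, "nucleus_radius", lower = 0, allow_zero = FALSE)
  check_number(min_separation, "min_separation", lower = 0)
  if (is.null(names(channels)) || anyDuplicated(names(channels))) {
    stop_gastr("`channels` must be a uniquely named list.", "parameter_error")
  }
  ok <- vapply(channels, inherits, logical(1), "pattern_params")
  if (!all(ok)) {
    stop_gastr("every channel must be a `pattern_params` object.",
               "parameter_error")
  }
  structure(
    list(radius = radius, density = density, nucleus_radius = nucleus_radius,
         channels = channels, seed = as.integer(seed),
         min_separation = min_separation),
    class = "colony_spec"
  )
}

#' Sample a synthetic colony as a nucleus point table
#'
#' Places `round(density * disc area)` nucleus centres uniformly on the disc
#' (rejection sampling with an optional hard-core minimum separation of one
#' nucleus diameter), then draws each nucleus's per-channel intensity from
#' the channel's radial field at the nucleus's depth plus Gaussian noise,
#' clipped at zero.
#'
#' @param spec A [colony_spec()].
#' @return A tibble with one row per nucleus: `nucleus_id`, `x_um`, `y_um`
#'   (colony centre at the origin), `depth_um`, and one intensity column per
#'   channel.
#' @examples
#' tbl <- sample_colony(colony_spec(density = 300, seed = 7))
#' nrow(tbl)
#' @export
sample_colony <- function(spec) {
  stopifnot(inherits(spec, "colony_spec"))
  area_mm2 <- pi * (spec$radius / 1000)^2
  n <- round(spec$density * area_mm2)
  if (n == 0) {
    out <- tibble::tibble(nucleus_id = integer(), x_um = numeric(),
                          y_um = numeric(), depth_um = numeric())
    for (ch in names(spec$channels)) out[[ch]] <- numeric()
    return(out)
  }
  withr::with_seed(spec$seed, {
    xs <- numeric(n); ys <- numeric(n)
    placed <- 0L
    attempts <- 0L
    max_attempts <- 200L * n
    min_sep2 <- spec$min_separation^2
    while (placed < n) {
      attempts <- attempts + 1L
      if (attempts > max_attempts) {
        stop_gastr(
          "could not place all nuclei at the requested density; hard-core separation is infeasible.",
          "infeasible_density")
      }
      x <- runif(1, -spec$radius, spec$radius)
      y <- runif(1, -spec$radius, spec$radius)
      if (x^2 + y^2 > spec$radius^2) next
      if (min_sep2 > 0 && placed > 0L) {
        d2 <- (xs[seq_len(placed)] - x)^2 + (ys[seq_len(placed)] - y)^2
        if (min(d2) < min_sep2) next
      }
      placed <- placed + 1L
      xs[placed] <- x; ys[placed] <- y
    }
    depth <- spec$radius - sqrt(xs^2 + ys^2)
    out <- tibble::tibble(nucleus_id = seq_len(n), x_um = xs, y_um = ys,
                          depth_um = depth)
    for (ch in names(spec$channels)) {
      p <- spec$channels[[ch]]
      mu <- radial_field(p, depth, radius = spec$radius)
      out[[ch]] <- pmax(0, mu + rnorm(n, sd = p$noise_sd))
    }
    out
  })
}

#' Render a nucleus table as a multi-channel image
#'
#' Each nucleus is drawn as a filled disc of `spec$nucleus_radius` at its
#' centre, in every channel. The DAPI channel (if present in the spec with a
#' zero-amplitude field it still renders its sampled value) uses the sampled
#' per-nucleus intensity like every other channel; additive Gaussian read
#' noise is applied per pixel and the image is clipped at zero.
#'
#' @param table Nucleus table from [sample_colony()].
#' @param spec The [colony_spec()] used to sample it.
#' @param pixel_size Micrometres per pixel (default 0.65).
#' @param read_noise_sd Per-pixel Gaussian read noise, arbitrary units.
#' @param margin Margin around the colony disc, micrometres.
#' @param noise_seed Integer seed for the read noise (defaults to
#'   `spec$seed + 1`, so render is reproducible but independent of sampling).
#' @return A `colony_image`: list with `channels` (named list of numeric
#'   matrices, dim 1 = x, dim 2 = y), `pixel_size_um`, and `extent_um`.
#' @export
render_colony <- function(table, spec, pixel_size = 0.65, read_noise_sd = 2,
                          margin = 10, noise_seed = spec$seed + 1L) {
  stopifnot(inherits(spec, "colony_spec"))
  check_number(pixel_size, "pixel_size", lower = 0, allow_zero = FALSE)
  check_number(read_noise_sd, "read_noise_sd", lower = 0)
  half <- spec$radius + margin
  n_px <- ceiling(2 * half / pixel_size)
  r_px <- spec$nucleus_radius / pixel_size
  chans <- lapply(spec$channels, function(p) matrix(0, n_px, n_px))
  if (nrow(table) > 0) {
    for (i in seq_len(nrow(table))) {
      cx <- um_to_px(table$x_um[i], n_px, pixel_size)
      cy <- um_to_px(table$y_um[i], n_px, pixel_size)
      ix <- max(1L, floor(cx - r_px)):min(n_px, ceiling(cx + r_px))
      iy <- max(1L, floor(cy - r_px)):min(n_px, ceiling(cy + r_px))
      d2 <- outer((ix - cx)^2, (iy - cy)^2, `+`)
      hit <- d2 <= r_px^2
      for (ch in names(chans)) {
        sub <- chans[[ch]][ix, iy, drop = FALSE]
        sub[hit] <- table[[ch]][i]
        chans[[ch]][ix, iy] <- sub
      }
    }
  }
  if (read_noise_sd > 0) {
    chans <- withr::with_seed(as.integer(noise_seed), {
      lapply(chans, function(m) pmax(m + rnorm(length(m),
                                               sd = read_noise_sd), 0))
    })
  }
  structure(
    list(channels = chans, pixel_size_um = pixel_size,
         extent_um = n_px * pixel_size, radius_um = spec$radius),
    class = "colony_image"
  )
}

#' Square-wave light stimulation schedule
#'
#' @param start,end Numeric vectors of ON-interval start and end times in
#'   hours; intervals must be sorted, disjoint and non-negative.
#' @return A `light_schedule` tibble with columns `start_h` and `end_h`.
#' @export
light_schedule <- function(start = numeric(), end = numeric()) {
  if (length(start) != length(end)) {
    stop_gastr("`start` and `end` must have equal length.", "parameter_error")
  }
  if (length(start)) {
    if (any(start < 0) || any(end <= start)) {
      stop_gastr("intervals need 0 <= start < end.", "parameter_error")
    }
    if (is.unsorted(start, strictly = TRUE) ||
        any(head(end, -1) > start[-1])) {
      stop_gastr("intervals must be sorted and disjoint.", "parameter_error")
    }
  }
  structure(tibble::tibble(start_h = as.numeric(start),
                           end_h = as.numeric(end)),
            class = c("light_schedule", class(tibble::tibble())))
}

#' Competence-window response parameters for the screen simulator
#'
#' The simulated mesoderm response to a WNT pulse integrates a Gaussian
#' competence kernel over instantaneous colony density: cells respond
#' maximally when their density is at `rho_star` during stimulation. BMP
#' priming multiplies the response by `bmp_gain`.
#'
#' @param rho_star Competence-peak density, cells/mm^2. Default 2400, the
#'   density at which WNT onset yields peak mesoderm.
#' @param kernel_sd Width of the competence kernel, cells/mm^2.
#' @param base_amplitude Response rate at peak competence, a.u./h.
#' @param bmp_gain Multiplicative BMP-priming gain, >= 1.
#' @param noise_sd Per-replicate Gaussian response noise, a.u.
#' @return A `competence_params` list.
#' @export
competence_params <- function(rho_star = 2400, kernel_sd = 500,
                              base_amplitude = 1, bmp_gain = 2,
                              noise_sd = 0.5) {
  check_number(rho_star, "rho_star", lower = 0, allow_zero = FALSE)
  check_number(kernel_sd, "kernel_sd", lower = 0, allow_zero = FALSE)
  check_number(base_amplitude, "base_amplitude", lower = 0)
  check_number(bmp_gain, "bmp_gain", lower = 1)
  check_number(noise_sd, "noise_sd", lower = 0)
  structure(list(rho_star = rho_star, kernel_sd = kernel_sd,
                 base_amplitude = base_amplitude, bmp_gain = bmp_gain,
                 noise_sd = noise_sd),
            class = "competence_params")
}

# Noise-free expected response for one (delay, duration) condition:
# gain * base_amplitude * integral over the light window of the competence
# kernel evaluated at instantaneous density. Fixed-step trapezoid at 0.1 h.
competence_response <- function(delay, duration, model, comp, bmp = FALSE,
                                dt = 0.1) {
  if (duration <= 0) return(0)
  t <- seq(delay, delay + duration, by = dt)
  if (t[length(t)] < delay + duration) t <- c(t, delay + duration)
  rho <- infer_density(t, model)
  k <- exp(-(rho - comp$rho_star)^2 / (2 * comp$kernel_sd^2))
  gain <- if (isTRUE(bmp)) comp$bmp_gain else 1
  w <- diff(t)
  gain * comp$base_amplitude * sum((head(k, -1) + k[-1]) / 2 * w)
}

#' Simulate a duration-by-delay optogenetic WNT screen
#'
#' For every valid (delay, duration) pair the expected mesoderm response is
#' the time-integral of a Gaussian competence kernel over instantaneous
#' colony density (see [competence_params()]); per-replicate observations add
#' Gaussian noise, clipped at zero. Conditions whose stimulation would run
#' past `experiment_length` are omitted, mirroring the triangular design of
#' a 48-hour differentiation.
#'
#' @param delays,durations Numeric vectors of onset delays and stimulus
#'   durations, hours. Defaults: delays 0-42 h, durations 6-48 h, step 6 h.
#' @param density_model A [density_model()] giving cells/mm^2 over time.
#' @param comp A [competence_params()].
#' @param bmp Logical: BMP4 priming arm?
#' @param replicates Replicate colonies per condition (default 10).
#' @param seed Integer seed.
#' @param experiment_length Total differentiation time, hours (default 48).
#' @param emit_colonies If `TRUE`, attach a list-column `colony` holding a
#'   sampled nucleus point table per replicate whose BRA amplitude equals the
#'   observed response (ring-patterned under BMP priming, uniform without),
#'   so image-level analyses can be exercised on screen output.
#' @param colony_density Density used for emitted colonies, cells/mm^2.
#' @return A tibble `(delay_h, duration_h, bmp, replicate, response)`,
#'   optionally with a `colony` list-column.
#' @export
simulate_screen <- function(delays = seq(0, 42, by = 6),
                            durations = seq(6, 48, by = 6),
                            density_model = gastruloidr::density_model(),
                            comp = competence_params(),
                            bmp = FALSE, replicates = 10, seed = 1L,
                            experiment_length = 48,
                            emit_colonies = FALSE, colony_density = 300) {
  if (!length(delays) || !length(durations)) {
    stop_gastr("`delays` and `durations` must be nonempty.", "parameter_error")
  }
  if (replicates < 1) {
    stop_gastr("`replicates` must be >= 1.", "parameter_error")
  }
  grid <- tidyr::crossing(delay_h = sort(unique(delays)),
                          duration_h = sort(unique(durations))) |>
    dplyr::filter(.data$delay_h + .data$duration_h <= experiment_length)
  grid$expected <- purrr::map_dbl(seq_len(nrow(grid)), function(i) {
    competence_response(grid$delay_h[i], grid$duration_h[i],
                        density_model, comp, bmp = bmp)
  })
  out <- withr::with_seed(as.integer(seed), {
    res <- tidyr::crossing(grid, replicate = seq_len(replicates)) |>
      dplyr::mutate(
        bmp = bmp,
        response = pmax(0, .data$expected +
                          rnorm(dplyr::n(), sd = comp$noise_sd))
      ) |>
      dplyr::select("delay_h", "duration_h", "bmp", "replicate", "response")
    if (emit_colonies) {
      res$colony <- purrr::map(seq_len(nrow(res)), function(i) {
        kind <- if (isTRUE(bmp)) "ring" else "uniform"
        sample_colony(colony_spec(
          density = colony_density,
          channels = list(BRA = pattern_params(
            kind, amplitude = res$response[i], background = 1, noise_sd = 1)),
          seed = sample.int(.Machine$integer.max, 1)
        ))
      })
    }
    res
  })
  out
}

#' Simulate a light-driven non-membrane beta-catenin time series
#'
#' First-order relaxation toward `plateau` while the light is on (rate
#' `k_on`) and back toward `baseline` while it is off (rate `k_off`),
#' stepped with the exact exponential update of the linear ODE, so interval
#' endpoints match the closed form.
#'
#' @param schedule A [light_schedule()].
#' @param k_on,k_off Relaxation rates, 1/h.
#' @param plateau,baseline Asymptotic intensities, arbitrary units.
#' @param dt Output time step, hours.
#' @param t_end End of the series, hours (default: end of the last ON
#'   interval plus one OFF relaxation, or 6 h for an empty schedule).
#' @return A `signaling_series` tibble `(t_h, value, light_on)` carrying the
#'   schedule as an attribute.
#' @export
simulate_bcat_series <- function(schedule, k_on = 1, k_off = 1, plateau = 100,
                                 baseline = 10, dt = 0.1,
                                 t_end = NULL) {
  stopifnot(inherits(schedule, "light_schedule"))
  check_number(k_on, "k_on", lower = 0, allow_zero = FALSE)
  check_number(k_off, "k_off", lower = 0, allow_zero = FALSE)
  check_number(dt, "dt", lower = 0, allow_zero = FALSE)
  if (is.null(t_end)) {
    t_end <- if (nrow(schedule)) max(schedule$end_h) + 6 else 6
  }
  t <- seq(0, t_end, by = dt)
  on <- rep(FALSE, length(t))
  for (i in seq_len(nrow(schedule))) {
    on <- on | (t >= schedule$start_h[i] & t < schedule$end_h[i])
  }
  v <- numeric(length(t))
  v[1] <- baseline
  for (i in seq_along(t)[-1]) {
    target <- if (on[i - 1]) plateau else baseline
    k <- if (on[i - 1]) k_on else k_off
    v[i] <- target + (v[i - 1] - target) * exp(-k * dt)
  }
  structure(
    tibble::tibble(t_h = t, value = v, light_on = on),
    schedule = schedule,
    class = c("signaling_series", class(tibble::tibble()))
  )
}
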