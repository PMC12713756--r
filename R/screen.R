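#' Exponential cell-density growth model
#'
#' Maps time since the start of differentiation to colony density,
#' `rho(t) = rho0 * 2^(t / doubling_time)` — the extrapolation used to
#' convert a WNT onset delay into an inferred instantaneous density.
#'
#' @param rho0 Density at t = 0, cells/mm^2 (default 1500, the standard
#'   seeding density).
#' @param doubling_time Population doubling time, hours (default 24, a
#'   representative hESC value; override from your own growth data).
#' @return A `density_model` object.
#' @export
density_model <- function(rho0 = 1500, doubling_time = 24) {
  check_number(rho0, "rho0", lower = 0, allow_zero = FALSE)
  check_number(doubling_time, "doubling_time", lower = 0, allow_zero = FALSE)
  structure(list(rho0 = rho0, doubling_time = doubling_time),
            class = "density_model")
}

#' Infer colony density at a given time
#'
#' @param t Time since differentiation start, hours (vectorised, >= 0).
#' @param model A [density_model()].
#' @return Density in cells/mm^2.
#' @examples
#' infer_density(24, density_model(rho0 = 1500, doubling_time = 24))
#' @export
infer_density <- function(t, model = density_model()) {
  stopifnot(inherits(model, "density_model"))
  if (any(t < 0)) {
    stop_gastr("`t` must be non-negative.", "domain_error")
  }
  model$rho0 * 2^(t / model$doubling_time)
}

#' Assemble a duration-by-delay screen grid from replicate records
#'
#' Cell value = mean over replicate colonies (each colony is one
#' experimental unit); SEM over replicates; conditions absent from the
#' records are `NA`, not zero. Conditions whose stimulation would outrun
#' the experiment are flagged `valid = FALSE`.
#'
#' @param records Tibble with columns `delay_h`, `duration_h`, `bmp`,
#'   `replicate`, `response` (one row per replicate colony).
#' @param experiment_length Total differentiation time, hours (default 48).
#' @return A `screen_grid` tibble in long format:
#'   `(delay_h, duration_h, bmp, mean, sem, n, valid)`.
#' @export
build_grid <- function(records, experiment_length = 48) {
  need <- c("delay_h", "duration_h", "bmp", "replicate", "response")
  if (!all(need %in% names(records))) {
    stop_gastr("`records` must have delay_h, duration_h, bmp, replicate, response.",
               "parameter_error")
  }
  dup <- records |>
    dplyr::count(.data$delay_h, .data$duration_h, .data$bmp,
                 .data$replicate) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup)) {
    stop_gastr("duplicate (delay, duration, replicate) records.",
               "ambiguity_error")
  }
  cells <- records |>
    dplyr::group_by(.data$delay_h, .data$duration_h, .data$bmp) |>
    dplyr::summarise(
      mean = mean(.data$response),
      sem = if (dplyr::n() > 1) sd(.data$response) / sqrt(dplyr::n())
            else NA_real_,
      n = dplyr::n(), .groups = "drop"
    )
  full <- tidyr::crossing(delay_h = sort(unique(records$delay_h)),
                          duration_h = sort(unique(records$duration_h)),
                          bmp = unique(records$bmp))
  grid <- full |>
    dplyr::left_join(cells, by = c("delay_h", "duration_h", "bmp")) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L),
                  valid = .data$delay_h + .data$duration_h <=
                    experiment_length) |>
    dplyr::arrange(.data$bmp, .data$duration_h, .data$delay_h)
  structure(grid, experiment_length = experiment_length,
            class = c("screen_grid", class(tibble::tibble())))
}

#' Normalise a screen grid to the BMP4-control mesoderm level
#'
#' Adds `normalized = mean / control_mean`; 1.0 means control-level
#' mesoderm.
#'
#' @param grid A [build_grid()] result.
#' @param control_mean Mean mesoderm intensity of BMP4 control colonies
#'   (> 0).
#' @return The grid with a `normalized` column.
#' @export
normalize_to_control <- function(grid, control_mean) {
  check_number(control_mean, "control_mean", lower = 0, allow_zero = FALSE)
  out <- dplyr::mutate(grid, normalized = mean / control_mean)
  attributes(out)$experiment_length <- attr(grid, "experiment_length")
  class(out) <- class(grid)
  out
}

#' Minimum WNT input reaching control-level mesoderm ("partial rescue")
#'
#' The smallest duration at which some delay reaches `normalized >= 1`;
#' among qualifying delays at that duration, the one with the highest
#' normalized response (ties to the smallest delay). If no condition
#' reaches control level an explicit no-rescue row is returned.
#'
#' @param grid A normalised [build_grid()] result.
#' @return A one-row tibble
#'   `(duration_h, delay_h, normalized, rescued)`.
#' @export
find_partial_rescue <- function(grid) {
  if (!"normalized" %in% names(grid)) {
    stop_gastr("grid has no `normalized` column; run normalize_to_control().",
               "parameter_error")
  }
  hits <- grid |>
    dplyr::filter(.data$valid, !is.na(.data$normalized),
                  .data$normalized >= 1)
  if (!nrow(hits)) {
    return(tibble::tibble(duration_h = NA_real_, delay_h = NA_real_,
                          normalized = NA_real_, rescued = FALSE))
  }
  best <- hits |>
    dplyr::filter(.data$duration_h == min(.data$duration_h)) |>
    dplyr::arrange(dplyr::desc(.data$normalized), .data$delay_h) |>
    dplyr::slice(1)
  tibble::tibble(duration_h = best$duration_h, delay_h = best$delay_h,
                 normalized = best$normalized, rescued = TRUE)
}

#' Density at the peak-response onset delay
#'
#' For one duration row of the screen, finds the delay with maximal mean
#' response and extrapolates the colony density at that onset through the
#' growth model. Flat rows break ties toward the smallest delay and are
#' flagged low-confidence. The grid's delay resolution bounds the
#' uncertainty: `density_step` reports the density growth over one delay
#' step at the recovered point.
#'
#' @param grid A [build_grid()] result.
#' @param model The [density_model()] describing growth in this experiment.
#' @param duration_row Duration (hours) selecting the grid row.
#' @return A one-row tibble `(duration_h, peak_delay_h, peak_density,
#'   delay_step_h, density_step, low_confidence)`.
#' @export
find_peak_density <- function(grid, model = density_model(),
                              duration_row = 6) {
  row <- grid |>
    dplyr::filter(.data$duration_h == duration_row, .data$valid,
                  !is.na(mean))
  if (!nrow(row)) {
    stop_gastr("no defined cells at this duration.", "insufficient_data")
  }
  mx <- max(row$mean)
  at <- sort(row$delay_h[row$mean == mx])
  tie <- length(at) > 1
  # flat-row guard: near-constant responses make the argmax meaningless
  flat <- (mx - min(row$mean)) <= 1e-12 * max(abs(mx), 1)
  delay_star <- at[1]
  delays <- sort(unique(row$delay_h))
  step <- if (length(delays) > 1) min(diff(delays)) else NA_real_
  dens <- infer_density(delay_star, model)
  dens_step <- if (is.na(step)) NA_real_ else
    infer_density(delay_star + step, model) - dens
  boundary <- delay_star == min(delays) || delay_star == max(delays)
  tibble::tibble(duration_h = duration_row, peak_delay_h = delay_star,
                 peak_density = dens, delay_step_h = step,
                 density_step = dens_step,
                 low_confidence = tie || flat || boundary)
}

#' BMP-priming differential between screen arms
#'
#' Elementwise difference of mean responses, BMP-primed minus unprimed,
#' over identical delay/duration axes; `NA` wherever either arm is
#' undefined.
#'
#' @param grid_bmp,grid_nobmp [build_grid()] results for the two arms.
#' @return A tibble `(delay_h, duration_h, delta, valid)`.
#' @export
bmp_prime_delta <- function(grid_bmp, grid_nobmp) {
  a <- dplyr::select(grid_bmp, "delay_h", "duration_h", mean_bmp = "mean",
                     "valid")
  b <- dplyr::select(grid_nobmp, "delay_h", "duration_h",
                     mean_nobmp = "mean")
  if (!identical(sort(unique(grid_bmp$delay_h)),
                 sort(unique(grid_nobmp$delay_h))) ||
      !identical(sort(unique(grid_bmp$duration_h)),
                 sort(unique(grid_nobmp$duration_h)))) {
    stop_gastr("the two grids have different delay/duration axes.",
               "incompatibility_error")
  }
  dplyr::inner_join(a, b, by = c("delay_h", "duration_h")) |>
    dplyr::mutate(delta = .data$mean_bmp - .data$mean_nobmp) |>
    dplyr::select("delay_h", "duration_h", "delta", "valid")
}

#' Fraction of conditions reaching a reference pattern class, per arm
#'
#' Summarises per-condition PFI phenotypes: the fraction of light
#' treatments in each BMP arm whose phenotype equals `reference_class`
#' (default `"high"`, i.e. comparable to BMP4-control patterning).
#'
#' @param results Tibble with columns `bmp` and `phenotype` (one row per
#'   condition).
#' @param reference_class Phenotype to count (default `"high"`).
#' @return A tibble `(bmp, n_conditions, fraction)`.
#' @export
pfi_class_fractions <- function(results, reference_class = "high") {
  if (!all(c("bmp", "phenotype") %in% names(results)) || !nrow(results)) {
    stop_gastr("`results` must be nonempty with bmp and phenotype columns.",
               "insufficient_data")
  }
  results |>
    dplyr::group_by(.data$bmp) |>
    dplyr::summarise(
      n_conditions = dplyr::n(),
      fraction = mean(.data$phenotype == reference_class),
      .groups = "drop"
    )
}
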