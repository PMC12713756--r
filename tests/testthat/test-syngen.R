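test_that("radial_field reproduces the closed-form field shapes", {
  u <- pattern_params("uniform", amplitude = 5, background = 10)
  expect_equal(radial_field(u, c(0, 100, 250)), rep(15, 3))

  r <- pattern_params("ring", ring_center_depth = 25, ring_sigma = 10,
                      amplitude = 100, background = 0)
  expect_equal(radial_field(r, 25), 100)
  expect_equal(radial_field(r, 35), 100 * exp(-1 / 2), tolerance = 1e-12)

  inv <- pattern_params("inverted", ring_sigma = 25, amplitude = 100,
                        background = 10)
  expect_equal(radial_field(inv, 250, radius = 250), 110)
  expect_lt(radial_field(inv, 0, radius = 250), 10 + 1e-6)

  a <- pattern_params("absent", background = 7)
  expect_equal(radial_field(a, c(0, 250)), c(7, 7))
})

test_that("radial_field rejects depths outside the colony", {
  p <- pattern_params("uniform")
  expect_error(radial_field(p, -1), class = "gastruloidr_range_error")
  expect_error(radial_field(p, 251, radius = 250),
               class = "gastruloidr_range_error")
})

test_that("sample_colony places round(density * area) nuclei on the disc", {
  spec <- colony_spec(seed = 1)
  tbl <- sample_colony(spec)
  # independent count: 1500 cells/mm^2 on a 0.25 mm radius disc
  expect_equal(nrow(tbl), round(1500 * pi * 0.25^2))
  expect_equal(nrow(tbl), 295)
  expect_true(all(tbl$x_um^2 + tbl$y_um^2 <= 250^2))
  expect_true(all(tbl$depth_um >= 0 & tbl$depth_um <= 250))
  # hard-core separation of one nucleus diameter
  d <- as.matrix(dist(cbind(tbl$x_um, tbl$y_um)))
  diag(d) <- Inf
  expect_gte(min(d), 2 * spec$nucleus_radius)
})

test_that("sample_colony handles degenerate densities", {
  expect_equal(nrow(sample_colony(colony_spec(density = 0))), 0)
  expect_error(
    sample_colony(colony_spec(radius = 50, density = 1e5, seed = 1)),
    class = "gastruloidr_infeasible_density")
})

test_that("colony sampling is deterministic in the seed and scales with density", {
  a <- sample_colony(colony_spec(density = 400, seed = 42))
  b <- sample_colony(colony_spec(density = 400, seed = 42))
  expect_identical(a, b)
  c2 <- sample_colony(colony_spec(density = 400, seed = 43))
  expect_false(identical(a, c2))
  area <- pi * 0.25^2
  n1 <- nrow(sample_colony(colony_spec(density = 400, seed = 1)))
  n2 <- nrow(sample_colony(colony_spec(density = 800, seed = 1)))
  expect_equal(n1, round(400 * area))
  expect_equal(n2, round(800 * area))
  expect_lte(abs(n2 - 2 * n1), 1)  # doubling is exact up to rounding
})

test_that("rotating a colony about its centre leaves the radial profile unchanged", {
  tbl <- sample_colony(colony_spec(density = 800, seed = 5))
  th <- 1.1
  rot <- dplyr::mutate(tbl,
                       x2 = cos(th) * x_um - sin(th) * y_um,
                       y2 = sin(th) * x_um + cos(th) * y_um,
                       x_um = x2, y_um = y2)
  disc <- fit_disc(tbl, known_radius = 250)
  disc0 <- tibble::tibble(cx_um = 0, cy_um = 0, radius_um = 250)
  class(disc0) <- class(disc)
  p1 <- bin_radial(edge_depth(tbl, disc0), "BRA", disc = disc0)
  p2 <- bin_radial(edge_depth(rot, disc0), "BRA", disc = disc0)
  expect_equal(p1$mean, p2$mean, tolerance = 1e-9)
  expect_equal(p1$n, p2$n)
})

test_that("render_colony draws nuclei as filled discs with read noise", {
  spec <- colony_spec(density = 0, seed = 1)
  img <- render_colony(sample_colony(spec), spec, read_noise_sd = 0)
  expect_true(all(img$channels$DAPI == 0))

  one <- tibble::tibble(nucleus_id = 1L, x_um = 0, y_um = 0, depth_um = 250,
                        DAPI = 100, BRA = 50)
  spec1 <- colony_spec(seed = 1)
  img1 <- render_colony(one, spec1, pixel_size = 1, read_noise_sd = 0)
  lit <- sum(img1$channels$DAPI > 0)
  expect_lt(abs(lit - pi * 5^2), 10)  # disc of ~79 px up to discretisation
  expect_equal(max(img1$channels$BRA), 50)
})

test_that("simulated screen response accumulates with duration and peaks at the competence density", {
  comp <- competence_params(noise_sd = 0)
  dm <- density_model(rho0 = 1500, doubling_time = 24)
  recs <- simulate_screen(delays = c(0, 6, 12, 18), durations = c(6, 12, 24),
                          density_model = dm, comp = comp, replicates = 1,
                          seed = 1)
  wide <- tidyr::pivot_wider(recs, id_cols = "delay_h",
                             names_from = "duration_h",
                             values_from = "response")
  expect_true(all(wide$`12` >= wide$`6`))
  expect_true(all(wide$`24` >= wide$`12`, na.rm = TRUE))

  # independent quadrature oracle for one cell
  k <- function(t) exp(-(infer_density(t, dm) - comp$rho_star)^2 /
                         (2 * comp$kernel_sd^2))
  oracle <- stats::integrate(k, 12, 18)$value
  got <- recs$response[recs$delay_h == 12 & recs$duration_h == 6]
  expect_equal(got, oracle, tolerance = 1e-4)

  # the short-duration response is maximal where density crosses rho_star
  r6 <- recs[recs$duration_h == 6, ]
  t_star <- 24 * log2(comp$rho_star / 1500)
  expect_equal(r6$delay_h[which.max(r6$response)],
               r6$delay_h[which.min(abs(r6$delay_h + 3 - t_star))])
})

test_that("screen replicates are reproducible and respect the triangular design", {
  a <- simulate_screen(replicates = 3, seed = 9)
  b <- simulate_screen(replicates = 3, seed = 9)
  expect_identical(a, b)
  expect_true(all(a$delay_h + a$duration_h <= 48))
  expect_true(all(a$response >= 0))
})

test_that("light schedules validate ordering and disjointness", {
  expect_s3_class(light_schedule(c(0, 12), c(6, 18)), "light_schedule")
  expect_error(light_schedule(c(0, 4), c(6, 10)),
               class = "gastruloidr_parameter_error")
  expect_error(light_schedule(5, 5), class = "gastruloidr_parameter_error")
})

test_that("beta-catenin series follows the first-order relaxation closed form", {
  empty <- simulate_bcat_series(light_schedule(), baseline = 10, t_end = 5)
  expect_true(all(empty$value == 10))

  on <- simulate_bcat_series(light_schedule(0, 200), plateau = 100,
                             baseline = 10, t_end = 200)
  expect_equal(on$value[length(on$value)], 100, tolerance = 1e-6)

  pulse <- simulate_bcat_series(light_schedule(0, 6), k_on = 1, plateau = 100,
                                baseline = 10, dt = 0.1, t_end = 12)
  expect_equal(pulse$value[pulse$t_h == 6],
               10 + 90 * (1 - exp(-6)), tolerance = 1e-9)
})
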