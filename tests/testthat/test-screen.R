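mkrecords <- function(df) {
  tibble::as_tibble(df)
}

test_that("build_grid averages replicates and leaves missing cells undefined", {
  recs <- mkrecords(data.frame(
    delay_h = c(0, 0, 6, 6), duration_h = c(6, 6, 6, 6), bmp = FALSE,
    replicate = c(1, 2, 1, 2), response = c(2, 4, 1, 3)))
  g <- build_grid(recs)
  expect_equal(g$mean[g$delay_h == 0], 3)
  expect_equal(g$sem[g$delay_h == 0], sd(c(2, 4)) / sqrt(2))

  # missing condition stays NA, not zero
  recs2 <- dplyr::bind_rows(recs, tibble::tibble(
    delay_h = 12, duration_h = 12, bmp = FALSE, replicate = 1, response = 9))
  g2 <- build_grid(recs2)
  missing_cell <- g2[g2$delay_h == 0 & g2$duration_h == 12, ]
  expect_true(is.na(missing_cell$mean))
  expect_equal(missing_cell$n, 0L)

  # record order never matters
  g3 <- build_grid(recs2[sample.int(nrow(recs2)), ])
  expect_equal(g3, g2)

  expect_error(build_grid(dplyr::bind_rows(recs, recs[1, ])),
               class = "gastruloidr_ambiguity_error")
})

test_that("conditions that outrun the experiment are flagged invalid", {
  recs <- simulate_screen(replicates = 2, seed = 1)
  g <- build_grid(recs)
  expect_true(all(g$valid == (g$delay_h + g$duration_h <= 48)))
  expect_true(all(is.na(g$mean[!g$valid])))
})

test_that("normalisation to control rescales without reordering", {
  recs <- mkrecords(data.frame(delay_h = c(0, 6), duration_h = 6,
                               bmp = FALSE, replicate = 1,
                               response = c(25, 10)))
  g <- normalize_to_control(build_grid(recs), control_mean = 10)
  expect_equal(sort(g$normalized), c(1, 2.5))
  expect_equal(which.max(g$normalized), which.max(g$mean))
  expect_error(normalize_to_control(build_grid(recs), 0),
               class = "gastruloidr_parameter_error")
})

test_that("find_partial_rescue returns the minimum sufficient WNT input", {
  grid <- build_grid(mkrecords(expand.grid(
    delay_h = c(0, 6, 12, 18), duration_h = c(6, 12, 18), bmp = FALSE,
    replicate = 1)) |>
      dplyr::mutate(response = 5))
  # plant: only (duration 12, delay 18) and (duration 18, delay 0) reach 1.0
  grid$mean[grid$duration_h == 12 & grid$delay_h == 18] <- 20
  grid$mean[grid$duration_h == 18 & grid$delay_h == 0] <- 30
  g <- normalize_to_control(grid, 15)
  res <- find_partial_rescue(g)
  expect_true(res$rescued)
  expect_equal(res$duration_h, 12)
  expect_equal(res$delay_h, 18)

  none <- find_partial_rescue(normalize_to_control(grid, 1000))
  expect_false(none$rescued)
  expect_true(is.na(none$duration_h))

  # invariance under a common positive rescale of data and control
  g2 <- normalize_to_control(
    dplyr::mutate(grid, mean = mean * 3.7), 15 * 3.7)
  class(g2) <- class(g)
  expect_equal(find_partial_rescue(g2)$delay_h, res$delay_h)
  expect_equal(find_partial_rescue(g2)$duration_h, res$duration_h)
})

test_that("density extrapolation follows the doubling law exactly", {
  dm <- density_model(rho0 = 1500, doubling_time = 24)
  expect_equal(infer_density(0, dm), 1500)
  expect_equal(infer_density(24, dm), 3000)
  expect_equal(infer_density(48, dm), 6000)
  t <- c(3, 17.5, 40)
  expect_equal(infer_density(t + 24, dm), 2 * infer_density(t, dm))
  expect_error(infer_density(-1, dm), class = "gastruloidr_domain_error")
})

test_that("find_peak_density maps the argmax delay through the growth model", {
  recs <- mkrecords(data.frame(delay_h = c(0, 6, 12, 18, 24),
                               duration_h = 6, bmp = FALSE, replicate = 1,
                               response = c(1, 3, 9, 4, 2)))
  g <- build_grid(recs)
  pk <- find_peak_density(g, density_model(1500, 24), duration_row = 6)
  expect_equal(pk$peak_delay_h, 12)
  expect_equal(pk$peak_density, 1500 * 2^0.5, tolerance = 1e-9)
  expect_false(pk$low_confidence)

  flat <- build_grid(mkrecords(data.frame(
    delay_h = c(0, 6, 12), duration_h = 6, bmp = FALSE, replicate = 1,
    response = 2)))
  pf <- find_peak_density(flat, density_model(1500, 24), 6)
  expect_equal(pf$peak_delay_h, 0)
  expect_true(pf$low_confidence)

  expect_error(find_peak_density(g, duration_row = 99),
               class = "gastruloidr_insufficient_data")
})

test_that("the BMP-priming differential mirrors the generator gain", {
  comp0 <- competence_params(noise_sd = 0, bmp_gain = 2)
  dm <- density_model()
  g_no <- build_grid(simulate_screen(density_model = dm, comp = comp0,
                                     bmp = FALSE, replicates = 1, seed = 2))
  g_yes <- build_grid(simulate_screen(density_model = dm, comp = comp0,
                                      bmp = TRUE, replicates = 1, seed = 2))
  delta <- bmp_prime_delta(g_yes, g_no)
  ok <- !is.na(delta$delta)
  expect_equal(delta$delta[ok], g_no$mean[ok], tolerance = 1e-9)

  same <- bmp_prime_delta(g_no, g_no)
  expect_true(all(same$delta[!is.na(same$delta)] == 0))

  g_off <- build_grid(simulate_screen(delays = c(0, 6), durations = c(6),
                                      density_model = dm, comp = comp0,
                                      replicates = 1, seed = 2))
  expect_error(bmp_prime_delta(g_yes, g_off),
               class = "gastruloidr_incompatibility_error")
})

test_that("pfi_class_fractions counts reference-class conditions per arm", {
  res <- tibble::tibble(
    bmp = rep(c(TRUE, FALSE), c(20, 20)),
    phenotype = c(rep("high", 7), rep("low", 13), rep("uniform", 20)))
  fr <- pfi_class_fractions(res)
  expect_equal(fr$fraction[fr$bmp], 0.35)
  expect_equal(fr$fraction[!fr$bmp], 0)
  all_high <- pfi_class_fractions(tibble::tibble(bmp = TRUE,
                                                 phenotype = "high"))
  expect_equal(all_high$fraction, 1)
  expect_error(pfi_class_fractions(tibble::tibble()),
               class = "gastruloidr_insufficient_data")
})

test_that("screen arms generated as rings vs uniform separate in PFI class", {
  # +BMP colonies carry an edge ring, -BMP colonies a uniform field
  res <- purrr::map_df(1:6, function(s) {
    ring <- truth_pfi(sample_colony(phenotype_spec("ring", seed = s,
                                                   density = 600)))
    unif <- truth_pfi(sample_colony(phenotype_spec("uniform", seed = s,
                                                   density = 600)))
    dplyr::bind_rows(dplyr::mutate(ring, bmp = TRUE),
                     dplyr::mutate(unif, bmp = FALSE))
  })
  fr <- pfi_class_fractions(res)
  expect_equal(fr$fraction[fr$bmp], 1)
  expect_equal(fr$fraction[!fr$bmp], 0)
})
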