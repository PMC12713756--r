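mkdisc <- function(r = 250) {
  structure(tibble::tibble(cx_um = 0, cy_um = 0, radius_um = r),
            class = c("colony_disc", class(tibble::tibble())))
}

mkprofile <- function(means, w = 10, r = 250) {
  n <- length(means)
  structure(
    tibble::tibble(channel = "BRA", bin_lo_um = (seq_len(n) - 1) * w,
                   bin_hi_um = seq_len(n) * w, mean = means,
                   sem = NA_real_, n = ifelse(is.na(means), 0L, 5L)),
    radius_um = r, bin_width_um = w,
    class = c("radial_profile", class(tibble::tibble())))
}

test_that("region_mean averages the bins inside a micrometre window", {
  prof <- mkprofile(rep(3.5, 25))
  expect_equal(region_mean(prof, c(10, 40)), 3.5)
  expect_equal(region_mean(prof, c(210, 240)), 3.5)

  prof2 <- mkprofile(c(NA, 2, 4, 6, rep(NA, 21)))
  expect_equal(region_mean(prof2, c(10, 40)), 4)
  expect_error(region_mean(prof2, c(100, 150)),
               class = "gastruloidr_empty_region")
  expect_error(region_mean(prof, c(300, 400)),
               class = "gastruloidr_empty_region")

  # n-weighted option
  prof3 <- mkprofile(c(2, 4, rep(NA, 23)))
  prof3$n[1:2] <- c(1L, 3L)
  expect_equal(region_mean(prof3, c(0, 20), weighted = TRUE), 3.5)
})

test_that("compute_pfi is the bounded edge-centre contrast", {
  expect_equal(compute_pfi(5, 5), 0)
  expect_equal(compute_pfi(5, 0), 1)
  expect_equal(compute_pfi(0, 5), -1)
  expect_equal(compute_pfi(2, 1), 1 / 3)
  expect_true(is.na(compute_pfi(0, 0)))
  expect_error(compute_pfi(-1, 2), class = "gastruloidr_domain_error")
})

test_that("compute_pfi is scale-invariant, antisymmetric and bounded", {
  withr::with_seed(7, {
    e <- runif(200, 0, 100)
    c0 <- runif(200, 0, 100)
    k <- runif(200, 0.01, 50)
    expect_equal(compute_pfi(k * e, k * c0), compute_pfi(e, c0),
                 tolerance = 1e-12)
    expect_equal(compute_pfi(e, c0), -compute_pfi(c0, e), tolerance = 1e-12)
    v <- compute_pfi(e, c0)
    expect_true(all(v >= -1 & v <= 1, na.rm = TRUE))
  })
})

test_that("classification thresholds partition the PFI range", {
  expect_equal(classify_pfi(0.5), "high")     # BMP4-level fidelity > 0.32
  expect_equal(classify_pfi(0.2), "low")
  expect_equal(classify_pfi(-0.5), "inverted")
  expect_equal(classify_pfi(0.0), "uniform")
  # boundary convention: closed on the uniform side, 0.32 maps low
  expect_equal(classify_pfi(c(-0.1, 0.1, 0.32, NA)),
               c("uniform", "uniform", "low", "undefined"))
  # the partition is total over a dense sweep
  sweep <- seq(-1, 1, by = 0.001)
  cls <- classify_pfi(sweep)
  expect_true(all(cls %in% c("inverted", "uniform", "low", "high")))
})

test_that("pfi_from_profile recovers the generating phenotype from point tables", {
  for (kind in c("ring", "inverted", "uniform")) {
    tbl <- sample_colony(phenotype_spec(kind, seed = 11))
    res <- truth_pfi(tbl)
    expect_equal(res$phenotype, expected_class(kind), label = kind)
  }
  # target-dialect ring peaked in the 50-80 um band
  tblt <- sample_colony(phenotype_spec("ring", seed = 11, dialect = "target"))
  rest <- truth_pfi(tblt, dialect = "target")
  expect_equal(rest$phenotype, "high")
  expect_equal(rest$dialect, "target")
})

test_that("annulus_pfi reproduces indicator-image values", {
  n <- 200
  disc <- mkdisc(r = 90)
  const <- matrix(7, n, n)
  res <- annulus_pfi(const, disc, pixel_size = 1, edge_offsets = c(20, 40),
                     center_region = c(70, 90))
  expect_equal(res$edge_mean, 7, tolerance = 1e-9)
  expect_equal(res$center_mean, 7, tolerance = 1e-9)
  expect_equal(res$pfi, 0)

  # 1 inside the annulus band, 0 elsewhere
  x <- (seq_len(n) - 0.5) - n / 2  # pixel-centre coordinates, origin centred
  depth <- 90 - sqrt(outer(x^2, x^2, `+`))
  ind <- matrix(0, n, n)
  ind[depth >= 20 & depth < 40] <- 1
  res2 <- annulus_pfi(ind, disc, pixel_size = 1, edge_offsets = c(20, 40),
                      center_region = c(70, 90))
  expect_equal(res2$edge_mean, 1, tolerance = 0.05)
  expect_lt(res2$center_mean, 1e-9)
  expect_equal(res2$pfi, 1, tolerance = 0.05)

  expect_error(annulus_pfi(const, disc, edge_offsets = c(95, 120)),
               class = "gastruloidr_geometry_error")
})

test_that("annulus and profile PFI agree on a rendered ring colony", {
  spec <- phenotype_spec("ring", seed = 4, dialect = "target")
  tbl <- sample_colony(spec)
  img <- render_colony(tbl, spec)
  nuc <- segment_colony(img)
  disc <- fit_disc(nuc)
  prof_res <- pfi_from_profile(
    bin_radial(edge_depth(nuc, disc), "BRA", disc = disc),
    edge_region = c(50, 80))
  ann_res <- annulus_pfi(
    subtract_background(img$channels$BRA, pixel_size = 0.65),
    disc, pixel_size = 0.65, edge_offsets = c(51, 80))
  expect_lt(abs(ann_res$pfi - prof_res$pfi), 0.1)  # 10% of the PFI scale
  expect_equal(ann_res$phenotype, "high")
})
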