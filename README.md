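# gastruloidr

Quantification of germ-layer patterning in micropatterned 2D gastruloids.

Human pluripotent stem cells confined on 500 µm micropatterned discs and
stimulated with BMP4 self-organise into concentric germ-layer rings: an
outer extraembryonic band (GATA3), a mesoderm ring (Brachyury/BRA) a few
cell widths in from the edge, and an ectoderm core (SOX2). Experiments that
perturb WNT signalling in time and space — for example optogenetic delivery
with a chosen onset delay and duration — read out their effect as changes
in this radial architecture. `gastruloidr` provides the quantification
pipeline for such experiments:

* **nuclei segmentation** on the DAPI channel (background subtraction,
  thresholding, watershed splitting, size/circularity gating) and
  per-nucleus marker measurement;
* **radial profiling** — marker intensity binned by distance from the
  colony edge (10 µm bins), with replicate-averaged profiles and colony
  averaging;
* the **Pattern Fidelity Index**,

  ```
  PFI = (Edge − Center) / (Edge + Center)
  ```

  the bounded contrast between the mean BRA intensity in a defined edge
  band and at the colony centre, with phenotype classification
  (PFI > 0.32 high fidelity, 0.1–0.32 low, |PFI| ≤ 0.1 uniform,
  PFI < −0.1 inverted patterning);
* **duration × delay screen analysis** — heatmap grids over WNT onset
  delay and duration, normalisation to the BMP4 control level, the
  minimum-input "partial rescue" search, and extrapolation of colony
  density at the response peak through an exponential growth model
  `ρ(t) = ρ₀·2^(t/Td)`;
* **non-membrane β-catenin** quantification (the signalling-active pool)
  via cell territories and boundary-band exclusion, plus light-driven
  signalling time-series summaries;
* a **synthetic colony and screen generator** that emulates all of the
  above with known ground truth, so every stage is validated end to end.

All user-facing functions take and return tibbles and chain with the pipe;
result types have `autoplot()`, `tidy()` and `glance()` methods.

## Worked example

Generate a BMP4-like synthetic colony (BRA ring peaked 65 µm in from the
edge), render it to an image, and run the full pipeline back to a PFI:

```r
library(gastruloidr)

spec <- colony_spec(
  density = 1500,   # cells/mm^2
  channels = list(
    DAPI = pattern_params("uniform", amplitude = 100, background = 0,
                          noise_sd = 5),
    BRA  = pattern_params("ring", ring_center_depth = 65, ring_sigma = 15)
  ),
  seed = 42
)
analyze_colony(spec, dialect = "target")
#> # A tibble: 1 × 7
#>   n_true n_detected edge_mean center_mean   pfi phenotype dialect
#>    <int>      <int>     <dbl>       <dbl> <dbl> <chr>     <chr>
#> 1    295        292      53.7        8.41 0.729 high      target
```

295 nuclei were placed, 292 recovered by segmentation; the edge band
(50–80 µm from the edge) is 6.4× brighter than the centre, giving
PFI = 0.729 — "high" pattern fidelity, as expected for a colony whose ring
sits in the BMP4 target band.

A simulated duration × delay optogenetic screen, and the colony density at
which a short WNT pulse is most effective:

```r
dm   <- density_model(rho0 = 1500, doubling_time = 24)
grid <- simulate_screen(density_model = dm, comp = competence_params(),
                        bmp = TRUE, replicates = 10, seed = 42) |>
  build_grid()
find_peak_density(grid, dm, duration_row = 6)
#> # A tibble: 1 × 6
#>   duration_h peak_delay_h peak_density delay_step_h density_step low_confidence
#>        <dbl>        <dbl>        <dbl>        <dbl>        <dbl> <lgl>
#> 1          6           12        2121.            6         401. FALSE
```

A 6-hour pulse is most effective with a 12-hour onset delay, when the
colony has grown to ≈ 2121 cells/mm² — within one 6-hour grid step of the
simulator's competence peak at 2400 cells/mm².

An end-to-end run (colonies, screen, heatmap, provenance-stamped CSVs) is
driven by a single YAML config:

```r
run_pipeline(system.file("extdata", "demo_config.yml",
                         package = "gastruloidr"),
             out_dir = "demo-out")
```

or from a shell via `inst/scripts/run_pipeline.R`.

## Vignette

`vignettes/pattern-fidelity.Rmd` documents the generative model, the
quantification conventions (bin geometry, edge-region dialects, threshold
boundaries), the numerical choices, and known limitations.
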