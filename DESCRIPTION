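Package: gastruloidr
Title: Quantification of Germ-Layer Patterning in Micropatterned 2D Gastruloids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to read germ-layer patterning out of micropatterned
    2D-gastruloid images: nuclei segmentation and per-nucleus marker
    measurement, distance-from-edge radial intensity profiling, the Pattern
    Fidelity Index (PFI) with phenotype classification, duration-by-delay
    optogenetic screen analysis with cell-density extrapolation, and
    quantification of the non-membrane (signaling-active) beta-catenin pool.
    Includes a synthetic colony and screen generator that emulates the
    statistical structure of micropattern experiments, so every stage of the
    pipeline can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    EBImage,
    tiff,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
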