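Package: strucell
Title: Structured Microenvironments, Depth-Averaged Flow and Single-Cell
    Stress Exposure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how micrometre-scale environmental structure
    shapes the exposure of individual microbial cells to dissolved stressors
    in microfluidic systems. Generates rasterised structured scenes (mock
    object arrays, pillar-bounded cell traps with microspheres, and soil
    micromodel channels), solves a depth-averaged interpolated thick/thin
    limit (Stokes-Brinkman) flow model on them with a staggered-grid
    multigrid solver, computes Voronoi-tessellation and greyscale
    distance-map spatial metrics for cells among obstacles, simulates
    calibrated single-cell copper-reporter responses with lognormal
    cell-to-cell noise, and summarises structure-exposure-response
    relationships (coefficients of variation, Pearson correlations, binned
    response profiles) in reproducible end-to-end experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    png,
    tiff,
    ggplot2,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    minpack.lm,
    withr,
    optparse
Config/testthat/edition: 3
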