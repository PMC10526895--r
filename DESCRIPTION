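Package: hdperim
Title: High-Density Perimetry Simulation, Analysis and Adaptive Scotoma Search
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for simulating and analysing high-density static perimetry
    of a small visual-field region around the optic nerve head. Implements
    ZEST Bayesian adaptive contrast-threshold estimation on a dense test grid,
    eye-position-based trial filtering from per-frame fundus-image
    displacements, three result displays (conventional threshold map,
    kernel-weighted local maximum-likelihood threshold map, and the crossover
    "slice" display with a display-threshold sweep), and a wave-based adaptive
    search that traces scotoma boundaries outward from the blind spot using
    Voronoi neighbourhoods. A synthetic-observer module generates ground-truth
    sensitivity surfaces with a blind spot and vessel angioscotomas, plus full
    simulated sessions with fixational eye movements, so every analysis is
    testable against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
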