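Package: fluctrack
Title: Fluorescence Fluctuation Spectroscopy and Vesicle Tracking for
    Two-Photon Time-Lapse Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis tools for quantifying sterol transport
    in two-photon time-lapse microscopy. Implements temporal and raster
    image correlation spectroscopy (TICS, RICS), number and brightness
    (N&B) moment analysis, multiple-particle tracking with
    Laplacian-of-Gaussian spot detection, 2D Gaussian vesicle sizing, and
    mean-square-displacement model fitting for combined anomalous
    subdiffusion (fractional Brownian motion) and directed transport. A
    synthetic-data engine generates fractional-Brownian-motion
    trajectories with drift, reaction-diffusion simulations of monomers
    binding to slow vesicle-like structures, and photon-count image
    stacks in snapshot and raster-scan acquisition, so every analysis
    stage can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    graphics,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
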