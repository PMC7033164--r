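Package: psobp
Title: Photosynthetic Rate Prediction for Young Canopy Leaves with
    PSO-Initialised Backpropagation Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling the net photosynthetic rate (Pn) of young
    (newly emerged) canopy leaves from greenhouse environmental drivers.
    Provides a synthetic full-factorial experiment generator emulating
    temperature x CO2 x light response surfaces and chlorophyll fluorescence
    parameters (qP, ETR, PhiPS2, Fv'/Fm', NPQ, qN); Pearson correlation
    screening with significance flags; a from-scratch single-hidden-layer
    backpropagation network with gradient-descent and damped least-squares
    (Levenberg-Marquardt) training; a particle swarm optimiser over flattened
    network weights used to choose initial weights (PSO-BP); and an
    evaluation pipeline comparing plain BP against PSO-BP and fitting
    auxiliary fluorescence-parameter (ETR, NPQ) prediction models.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
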