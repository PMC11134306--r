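Package: neflow
Title: Spatiotemporal Analysis of Norepinephrine Sensor Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for two-channel two-photon movies of a green
    norepinephrine (NE) sensor (GRAB-NE2h) and a red calcium indicator
    (jRGECO1a): registration, bleed-through correction, perineuronal
    annulus/global field construction, spatial autocorrelation of the NE
    field, sliding-window NE synchrony, Horn-Schunck optic-flow extraction
    of release/reuptake events, per-cell regression models of calcium
    activity on NE fields, and linear mixed-effects drug-condition
    comparisons. Includes a synthetic movie generator with known ground
    truth (event times, locations, coupling coefficients) for validating
    every stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    Rcpp,
    jsonlite,
    tiff,
    minpack.lm,
    lme4,
    lmerTest
LinkingTo:
    Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
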