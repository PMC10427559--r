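Package: plaquesim
Title: Lipid-Structured Simulation of Atherosclerotic Plaque Macrophages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulator for a lipid-structured population model of
    atherosclerotic plaque macrophages. Live macrophages are structured by
    ingested lipid load and governed by a nonlocal advection-reaction
    partial integro-differential equation coupled to a linear equation for
    apoptotic cells and an ordinary differential equation for necrotic
    lipid. Apoptosis, emigration and proliferation rates may depend on
    lipid load through saturating or peaked modulating functions. Provides
    a method-of-lines solver with upwind advection and an efferocytosis
    convolution source, steady-state detection and oscillation
    classification, moment and lipid-ledger diagnostics with independent
    ODE oracles, calibration of modulation scalings to a target
    population-averaged rate, and a registry of named scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
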