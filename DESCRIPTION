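Package: sfkin
Title: Stopped-Flow Fluorescence Kinetics of Sequential Enzyme Mechanisms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Pre-steady-state kinetic analysis of enzyme-DNA interactions
    observed by stopped-flow fluorescence. Builds sequential mass-action
    mechanisms (bimolecular binding, isomerizations, irreversible chemistry,
    product release), integrates them with a stiff solver, maps species
    trajectories to fluorescence through a linear observation model, and
    estimates rate constants by global multi-start nonlinear least squares
    over concentration series. Includes quadratic-isotherm fitting of
    equilibrium titrations, closed-form derived constants (composite
    association constant, observed single-turnover rate, half-conversion
    time), nested-model selection by sequential complication, and a seeded
    synthetic-data generator for validation by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
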