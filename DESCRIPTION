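Package: powerfate
Title: Power-Law Modeling of Cell-Fate Probabilities from Signaling Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Data-driven modeling of cell-fate decisions (e.g. apoptosis)
    from phosphoproteomic signaling measurements.  Fits a nonlinear
    power-law (S-system style) model that relates the probability of a
    cell fate to a product of protein activities raised to fitted
    exponents, alongside the conventional linear baseline, both estimated
    by partial least squares regression.  Includes protein-on-protein
    influence-matrix estimation, in-silico protein knock-down for
    drug-effect identification, single-variable curve-family comparison,
    Kullback-Leibler and AIC model evaluation, repeated cross-validation
    protocols, time-staggered input-output pairing, cell-line
    discrimination, and seeded generators for Boolean-network, power-law
    and ODE-cascade synthetic datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    yaml,
    minpack.lm,
    deSolve,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
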