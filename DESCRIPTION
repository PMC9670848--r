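Package: semifate
Title: Relative-Rate Chamber Kinetics and Two-Media Fate of a Semivolatile
    Photoproduct
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the environmental chemodynamics of
    4-isobutylacetophenone (IBAP), the toxic phototransformation product of
    ibuprofen (IBP). Implements relative-rate determination of gas-phase
    OH-radical rate constants from smog-chamber decay data, with wall-loss
    correction, inverse-variance weighted averaging and full uncertainty
    propagation; atmospheric descriptors (pseudo-first-order loss rates,
    lifetimes, steady-state OH from tetramethylethylene ozonolysis); and a
    closed-form two-media (surface water + atmosphere) first-order fate
    model giving time trends, the volatilized fraction, and per-pathway
    degradation fractions. Includes a synthetic-data generator for chamber
    decays and fate time series so every fitting stage is testable without
    experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    Matrix,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
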