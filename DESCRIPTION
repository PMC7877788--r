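Package: plsforest
Title: Settlement-Era Forest Structure from Public Land Survey Witness Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates settlement-era stem density, basal area, and
    aboveground biomass from Public Land Survey (PLS) witness-tree
    records. Implements point-level plotless density estimation
    (Morisita two-sector estimator with survey-design and size
    correction factors), log-log allometric biomass scaling,
    aggregation to a regular grid, a two-stage zero-inflated spatial
    model (binomial occupancy times log-scale potential, fit with
    penalized splines), quasi-Bayesian uncertainty via posterior
    coefficient draws, and a cross-validation protocol measuring
    weighted absolute error and prediction-interval coverage. Includes
    synthetic-data generators (marked spatial point processes sampled
    by the survey-corner protocol, and gridded occupancy/potential
    surfaces) used to exercise the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    mgcv,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
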