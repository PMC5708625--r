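Package: sdmbench
Title: Simulation Benchmarking of Presence-Background Species
    Distribution Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Generates virtual species on synthetic environmental
    landscapes, produces presence-only occurrence samples with controlled
    spatial clumping, reporting-rate filtering and geographic restriction,
    and benchmarks four presence-background species distribution model
    engines against point validation sets using AUC. The engines are
    a non-spatial Bayesian binomial GLM (Laplace approximation), a spatial
    Bayesian binomial GLM with a Gaussian Markov random field on a regular
    mesh (empirical-Bayes hyperparameter selection), boosted regression
    trees, and a MaxEnt-style L1-regularised feature-expansion model.
    Includes sample diagnostics (Clark-Evans dispersion, convex-hull
    coverage), scenario binning, configuration sweeps and a resumable
    seeded pipeline.
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
    MASS,
    Matrix,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr,
    xgboost
Suggests:
    glmnet,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
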