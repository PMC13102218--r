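Package: grmsim
Title: Monte Carlo Parameter-Recovery Simulation for the Graded Response Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation pipeline for studying how sample size, item count and
    response-category count determine parameter-recovery accuracy under the
    unidimensional graded response model (GRM). Generates finite populations of
    latent traits and item banks from the model's standard generating
    distributions, draws samples without replacement, fits the GRM by marginal
    maximum likelihood via the EM algorithm with fixed-grid quadrature, scores
    respondents by expected a posteriori (EAP) estimation, and summarises
    recovery with RMSE, finite-population-corrected and standardized RMSE, and
    Fisher-averaged correlations over a configurable condition grid.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    parallel
Config/testthat/edition: 3
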