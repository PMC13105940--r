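Package: geowaz
Title: Bayesian Geoadditive Modelling of Child Weight-for-Age Z-Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits Gaussian structured additive ("geoadditive") regression
    models for child anthropometric outcomes: penalized B-spline (P-spline)
    smooths of metrical covariates, an intrinsic Markov-random-field spatial
    effect over administrative regions, and parametric fixed effects, with
    fully Bayesian inference by Gibbs sampling under conjugate inverse-gamma
    hyperpriors. Includes deviance-information-criterion model comparison and
    stepwise term selection, credible-interval significance flags, MCMC and
    residual diagnostics, Yeo-Johnson screening profiles, inverse-distance-
    weighted hotspot interpolation, and a synthetic generator of DHS-like
    clustered survey data with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    graphics,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    splines,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    car,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
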