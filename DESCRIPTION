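Package: emacomplexity
Title: Complexity Markers for Ecological Momentary Assessment Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A battery of three complexity markers for single-subject ecological
    momentary assessment (EMA) self-rating time series: memory (Bartels rank
    randomness test, autocorrelation and partial autocorrelation profiles with
    significance counting, moving-window autocorrelation, and time-varying
    lag-1 autoregression with an effective-degrees-of-freedom non-stationarity
    criterion), regime shifts (KPSS level-stationarity test and energy-statistic
    divisive change-point detection with permutation significance), and
    sensitive dependence on initial conditions (delay-coordinate embedding and
    simplex-projection forecast skill with its decay slope). Includes a
    synthetic EMA generator with known ground truth (white noise, AR(1),
    fractional Gaussian noise, planted regime shifts with flickering, sine
    waves, the logistic map), Likert discretization and missing-data injection,
    and a per-item battery report with Bonferroni-corrected significance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mgcv,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
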