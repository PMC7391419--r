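Package: ppsrecal
Title: Rapid Recalibration of Peri-Personal Space: Simulation and Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying trial-by-trial ("rapid") recalibration of
    peri-personal space (PPS). Implements a firing-rate neural network of
    visuo-tactile PPS with Hebbian plasticity and a forgetting factor,
    sigmoid fitting of tactile reaction times against visuo-tactile
    distance with serial-dependence (history) splitting and an n-back
    gamma GLM, global field power (GFP) analysis of epoched EEG with
    paired-versus-summed supra-additivity contrasts, and seeded synthetic
    generators for behavioural sessions and multichannel evoked epochs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    minpack.lm,
    yaml,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
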