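Package: airplsopt
Title: Optimized and Learned Parameter Selection for airPLS Baseline
    Correction of Raman and SERS Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Baseline removal for Raman and surface-enhanced Raman (SERS)
    spectra built around the adaptive iteratively reweighted penalized
    least squares (airPLS) method. Provides a fast banded Whittaker
    solver with overflow-safe reweighting, an adaptive log-scale grid
    search that finds per-spectrum optimal smoothness and convergence
    parameters against a known true baseline, a synthetic SERS spectrum
    generator covering twelve peak-and-baseline shape classes with
    SNR-controlled Gaussian noise, evaluation metrics (mean absolute
    error, percentage improvement, confidence ellipses, parameter-region
    fits), and a PCA plus random-forest model that predicts near-optimal
    parameters directly from a raw spectrum. All user-facing functions
    take data frames and return tibbles.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    readr,
    signal,
    randomForest
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
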