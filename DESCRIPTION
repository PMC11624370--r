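Package: mefeval
Title: Genomic Evaluation of Methane Efficiency from Milk Mid-Infrared
    Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: End-to-end genomic evaluation pipeline for methane efficiency
    in dairy cattle: preprocessing of milk mid-infrared (MIR) spectra
    (informative-region selection, piecewise standardization, Mahalanobis
    quality control, Savitzky-Golay smoothing), prediction of daily methane
    production from spectra with a Bayesian-regularized neural network,
    multi-trait herd-test-day animal models solved by sparse mixed-model
    equations, AI-REML variance-component estimation, single-step GBLUP via
    the combined pedigree-genomic H matrix, and derivation of the methane
    efficiency (MEF) residual trait with relative breeding values,
    selection-index reliabilities and official-status rules. A synthetic
    data generator with known ground truth (gene dropping, Mendelian
    sampling, herd-test-day phenotypes, MIR-like spectra) makes every stage
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    Matrix,
    methods,
    purrr,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
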