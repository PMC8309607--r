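Package: ramanclean
Title: Denoising Low-SNR Raman Spectra with a Peak-Weighted Convolutional Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for removing shot noise from low signal-to-noise Raman
    spectra. Provides a Lorentzian-lineshape simulator with a Poisson
    shot-noise model for building large supervised training sets, a
    five-layer fully convolutional 1D denoising network trained with a
    custom loss that re-weights the window around the most prominent peak,
    Savitzky-Golay reference filters, and SNR-based evaluation metrics
    (global SNR, peak SNR and their product). Includes a command-line
    interface for simulation, training, denoising and head-to-head
    evaluation of denoisers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
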