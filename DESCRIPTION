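Package: specal
Title: Multivariate Spectral Calibration for Multicomponent Drug Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for simultaneous quantification of spectrally overlapping
    analytes from UV absorbance spectra. Implements the 25-run five-level
    five-factor multilevel calibration design, NIPALS partial least squares
    (PLS2) regression with leave-one-out cross-validation for latent-variable
    selection, a linear (purelin) feed-forward neural network calibrator, and
    a figures-of-merit layer (recoveries, RMSEP, SEP, predicted-versus-actual
    regression, LOD/LOQ, standard addition, and t/F method comparison).
    A Beer-Lambert simulator generates overlapping Gaussian-band spectra with
    instrument-like noise so that the full calibration workflow can be
    exercised and validated without a spectrophotometer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
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
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
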