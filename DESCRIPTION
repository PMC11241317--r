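Package: anthospec
Title: Micro-Hyperspectral Chemometrics for Anthocyanin Content Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A transmittance micro-hyperspectral imaging pipeline for
    predicting anthocyanin content in plant tissue. Covers black/white
    reference calibration of hypercubes and region-of-interest spectral
    extraction, spectral preprocessing (Savitzky-Golay smoothing, standard
    normal variate, polynomial detrending), wavelength selection by
    competitive adaptive reweighted sampling (CARS) and the successive
    projections algorithm (SPA), regression by NIPALS partial least squares
    and a one-dimensional convolutional neural network, and calibration
    model evaluation by Rc, RMSEC, Rp, RMSEP and RPD. Includes a synthetic
    spectra/cube generator with concentration-linked Gaussian absorption
    bands so the full pipeline is testable without instrument data, and
    ENVI raster input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    signal,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mixOmics
Config/testthat/edition: 3
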