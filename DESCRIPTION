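Package: plstraj
Title: Processing-Trajectory Optimization of PLS Calibration Models for NIR Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Systematic, exhaustive optimization of partial least squares (PLS)
    calibration models for near-infrared (NIR) spectra. Jointly searches the
    spectral pretreatment (standard normal variate, Savitzky-Golay smoothing
    and derivatives), the number of latent factors, and variable importance in
    projection (VIP) variable selection, scoring every path with RMSEC, RMSEP,
    R2 of calibration and validation, cross-validated RMSE, and RPD. Includes
    Kennard-Stone sample-set partitioning, a conventional one-parameter-at-a-time
    comparator, a generator of synthetic NIR-like spectra with known ground
    truth, readers and writers for delimited spectral tables and MATLAB v5
    containers, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    MASS,
    signal,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
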