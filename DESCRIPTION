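Package: libschemo
Title: Chemometric Variable Selection and Calibration for LIBS Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative elemental analysis of laser-induced breakdown
    spectroscopy (LIBS) spectra. Provides a synthetic emission-spectrum
    simulator with configurable line catalogs and noise mechanisms,
    Daubechies wavelet denoising, a rank-ordered calibration/prediction
    split, interval partial least squares (iPLS) and backward interval PLS
    (BiPLS) wavelength selection, the successive projections algorithm
    (SPA), univariate line calibration with intensity-ratio indices for
    internal standardization, and PLS and support-vector-machine
    multivariate calibration with cross-validated model selection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    data.table,
    e1071,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
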