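Package: fvfmspec
Title: Hyperspectral Prediction of Chlorophyll Fluorescence Fv/Fm and
    Drought-Tolerance Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Predicts the maximum photochemical quantum yield of
    photosystem II (Fv/Fm) from leaf hyperspectral reflectance with a
    compact one-dimensional convolutional neural network trained by
    seeded RMSProp on a mean-absolute-error loss, benchmarks it against
    classical regressors, and converts predictions into drought-tolerance
    coefficients with hierarchical-clustering-based genotype ranking.
    Includes Savitzky-Golay spectral preprocessing, reference-panel
    reflectance calibration, successive-projections-algorithm wavelength
    selection with Kennard-Stone sample splitting, the four standard
    chemometric error metrics, and a synthetic multi-genotype drought
    trial generator so the full pipeline can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    ape,
    caret,
    randomForest,
    ranger,
    rpart,
    testthat (>= 3.0.0),
    xgboost
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
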