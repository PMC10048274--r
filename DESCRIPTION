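Package: mirprofile
Title: Chemometric Calibration and Accuracy-Profile Validation for Milk Mid-Infrared Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying an analyte (linoleic acid) in milk from
    Fourier-transform mid-infrared (FT-MIR) absorbance spectra.  Provides a
    synthetic spectra generator with known ground truth, water-region masking
    and the standard chemometric preprocessing transforms (standard normal
    variate, Savitzky-Golay smoothing and derivatives), calibration models
    (NIPALS partial least squares, principal component regression, single
    hidden layer neural networks) with k-fold cross-validated grid search,
    random-forest response-permutation band selection, and ICH Q2(R1)-style
    method validation via beta-content tolerance intervals: limit of
    detection, trueness, repeatability and intermediate precision from
    one-way variance components, per-level tolerance limits, and the
    accuracy profile with interpolated lower and upper limits of
    quantification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ranger,
    nnet,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    signal,
    randomForest,
    optparse
Config/testthat/edition: 3
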