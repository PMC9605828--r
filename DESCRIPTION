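Package: nirproline
Title: Chemometric Calibration of Serum Proline from Near-Infrared Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying serum proline (mg/ml) from near-infrared
    absorbance spectra. Provides a seedable generator of serum-like spectra
    with known ground truth, derivative preprocessing (Savitzky-Golay and
    Norris gap-segment filters), outlier screening by Mahalanobis distance
    with Dixon's Q test and Chauvenet's criterion, Kennard-Stone
    calibration/validation partitioning, a NIPALS partial least squares
    engine with cross-validation, and three wavelength-selection strategies:
    stepwise multiple linear regression, interval PLS, and simulated
    annealing over a binary feature-retention vector with Metropolis
    acceptance. Model quality is reported with the standard multivariate
    calibration metrics (Rc, Rp, RMSEC, RMSEP, RMSECV, SEC, SEP, RPD,
    offset).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
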