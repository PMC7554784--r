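Package: ramanclass
Title: Peak-Based Classification of SERS Raman Spectra with Constrained Cross-Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A chemometrics pipeline for discriminating cell phenotypes from
    surface-enhanced Raman spectra: section-wise iterative-clipping polynomial
    baseline correction, maximum-peak normalization, local-maximum peak-matrix
    construction, univariate feature scoring (t-statistic, signal-to-noise
    'MIT' correlation, per-feature RELIEF) optionally chained with
    covariance-eigendecomposition PCA, and kNN/SVM classification under a
    class-constrained k-fold cross-validation suited to small imbalanced
    designs. Includes a seeded synthetic-spectrum generator with planted
    class-differential Lorentzian bands for end-to-end validation, and a
    wavenumber annotation table for marker reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
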