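Package: svmdx
Title: Clinical Utility of Maximum-Margin Classifiers for Case-Control Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Trains linear-kernel soft-margin (support-vector) classifiers on
    subject-by-feature case/control tables under leave-one-subject-out
    cross-validation, assesses significance by label permutation, and converts
    classifier output into clinically interpretable diagnostic indices:
    sensitivity, specificity, balanced accuracy, predictive values, the
    predictive summary index (PSI), the number needed to predict (NNP), the
    diagnostic odds ratio (DOR), and Cohen's kappa between classifiers.
    Includes Bayesian post-test probability updating with treat/discharge
    decision thresholds, and a synthetic paired-cohort generator that emulates
    back-to-back acquisitions of the same subjects at two noise levels (e.g.
    3T and 7T structural-MRI morphometry).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
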