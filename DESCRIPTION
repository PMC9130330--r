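Package: bosme
Title: Bayesian Network Over-Sampling for Imbalanced, Cost-Sensitive
    Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Over-sampling of the minority class in imbalanced binary
    data sets by forward sampling from a maximum-likelihood Bayesian
    network learned on the minority subset (discrete, Gaussian, or
    conditional linear Gaussian). Includes the cost-sensitive machinery
    that turns a misclassification-cost ratio into a target minority
    proportion via class-prior reweighting, a minimal SMOTE baseline, a
    repeated stratified cross-validation harness with paired
    significance testing, exact-binomial and trend summaries, and
    seeded synthetic-data generators with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    randomForest,
    e1071
Config/testthat/edition: 3
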