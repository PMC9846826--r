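Package: conformalscreen
Title: Mondrian Conformal Prediction for Imbalanced Bioactivity Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Uncertainty-aware QSAR screening for imbalanced bioactivity
    endpoints. Implements Mondrian (class-conditional) inductive conformal
    prediction around random-forest classifiers, with per-class calibration
    tables, conformal p-values, and four-way class assignment at a
    user-chosen significance level. Provides stratified cross-validated
    training with six imbalance-handling protocols (naive, equal-size
    under-sampling, duplication over-sampling, SMOTE, ROSE, conformal
    prediction) and a full binary-classification metrics panel; a
    multi-endpoint screening battery with confidence-tunable class
    assignment and out-of-domain flagging; and a prioritization layer that
    ranks library compounds against reference endocrine disruptors via
    binary conformal-p-value fingerprints (Tanimoto similarity) and t-SNE
    embedding of p-value profiles. A synthetic-data module generates
    imbalanced descriptor datasets and planted screening libraries with
    known ground truth. Chemistry input (SMILES standardization and
    physicochemical descriptors) is handled through Open Babel.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    randomForest,
    pROC,
    jsonlite,
    ChemmineR,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
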