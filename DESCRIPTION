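Package: cppuptake
Title: Quantitative Cell-Penetrating Peptide Uptake Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Featurization, benchmark curation, and regression modeling of
    quantitative cell-penetrating peptide (CPP) uptake. Builds a 2,908-column
    design matrix from whole-peptide physicochemical descriptors, position
    one-hot sequence encoding with anomalous-residue substitution, cell-line
    gene-mutation features, and experimental conditions (concentration,
    temperature, incubation, cargo); reproduces a six-step benchmark curation
    procedure with per-step accounting; and fits a nine-model regression zoo
    (SVM, SGD, kNN, decision tree, random forest, extremely randomized trees,
    gradient-boosted trees, a deep net, and a multi-branch forked net) with
    cross-validated hyperparameter search and six-metric evaluation. Includes
    a synthetic-data generator with a planted signal for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    yaml,
    jsonlite,
    e1071,
    rpart,
    ranger,
    xgboost,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
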