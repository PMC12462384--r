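Package: cpptools
Title: Cell-Penetrating Peptide Prediction from Sequence-Derived Descriptors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts whether short peptides are cell-penetrating (CPPs) and,
    for predicted CPPs, whether their cellular uptake efficiency is high or
    low. Sequences over the 20 canonical amino acids are encoded as a
    length-normalized descriptor vector (amino acid, dipeptide and tripeptide
    composition, k-spaced amino-acid group pairs, physicochemical scalars and
    atomic frequencies); features are screened with a Mann-Whitney rank test
    and ranked by extremely-randomized-trees impurity importance before a
    two-stage tree-ensemble classifier is fit. Includes stratified
    cross-validation, standard binary-classification metrics (sensitivity,
    specificity, accuracy, precision, F1, MCC, AUC), interpretability reports
    (top importances, per-block contributions, class frequency ratios,
    isoelectric-point/net-charge tables) and a seeded synthetic peptide
    generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    jsonlite,
    ranger,
    stats,
    tools,
    utils
Suggests:
    e1071,
    nnet,
    testthat (>= 3.0.0),
    xgboost
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
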