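Package: fldpr
Title: Profile-Based Prediction of Intrinsic Disorder and Disorder Function
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Per-residue prediction of intrinsic disorder and of four
    disorder functions (protein binding, DNA binding, RNA binding and
    flexible linkers) from sequence profiles. A 45-channel per-residue
    profile is encoded at three levels (residue window, averaging window,
    whole protein) into a 318-dimensional feature vector feeding a small
    feedforward deep network with a logistic-regression twin; disorder
    functions are assigned inside predicted disordered regions by random
    forests tuned under 3-fold cross-validation. Includes the full
    evaluation protocol (ROC-AUC by all-unique-threshold construction,
    MCC, F1, fully-disordered-protein calling, paired half-dataset
    resampling significance tests), a six-way ablation driver, and a
    synthetic-data generator so every stage is trainable and testable
    without external profile tools.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    ranger,
    glmnet,
    nortest,
    jsonlite,
    digest
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
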