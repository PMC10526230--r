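Package: hsnet3d
Title: Hierarchical Multi-Task 3D Convolutional Networks for Lung Nodule
    Attribute and Malignancy Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements HSNet, an interpretable hierarchical multi-task 3D
    convolutional network that predicts five radiologist-interpretable
    semantic attributes of a lung-nodule CT volume (calcification, margin,
    subtlety, texture, sphericity) and fuses them with learned image features
    into a benign/malignant prediction, together with the shared-extractor
    HSCNN baseline it improves on. Includes the full training recipe
    (axis-symmetry data augmentation from the 48-element cube symmetry group,
    cyclical learning rates, stochastic weight averaging, early-stopping
    checkpoint selection), a 4-fold cross-validation harness, evaluation
    statistics (confusion matrices, ROC-AUC, fold summaries, paired t tests,
    and a two-classifier error-rate significance statistic), and a synthetic
    3D nodule phantom generator whose voxel appearance is monotonically
    controlled by the ordinal attribute levels, so the entire pipeline is
    testable at desk scale on CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp,
    RNifti
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    pROC
Config/testthat/edition: 3
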