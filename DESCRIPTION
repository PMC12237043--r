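Package: falearn
Title: Focal Active Learning for Imbalanced Binary Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Pool-based focal active learning for imbalanced binary
    classification on tabular clinical data. Representative "foci" are
    selected from the unlabeled pool by k-means clustering under cosine
    similarity (spherical k-means); labeling batches are then chosen by a
    combined acquisition score mixing nearest-focus similarity, prediction
    uncertainty and minority-class priority; exact Shapley feature
    attributions drive an attention-style re-weighting of feature columns
    between iterations. Includes the surrounding preprocessing pipeline
    (deduplication, IQR outlier fences, label encoding, z-score
    standardization, stratified splitting), an evaluation toolkit
    (confusion-matrix metrics, stratified cross-validation, paired t-tests,
    ratio downsampling) and a synthetic generator emulating an imbalanced
    diabetes screening dataset so the whole method can be exercised without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    e1071,
    rpart,
    randomForest,
    xgboost,
    nnet
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
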