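Package: kerndr
Title: Kernel-Based Drug Repositioning with Convolutional Feature Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts drug-disease associations from a binary association
    matrix plus chemical-structure and disease-semantic similarities. Builds
    sigmoid interaction-profile kernels for drugs and diseases, rescales the
    side similarities with a logistic transform, boosts pairs that co-occur in
    cohesive modules of the co-association graph (ClusterONE-style greedy
    clustering), and fuses kernel and side similarities per pair. Each
    drug-disease pair is described by its fused similarity rows reshaped to a
    square grid, encoded by a small convolutional network trained on the
    association labels, and scored by a random forest (with an SVM
    comparator). Includes stratified ten-fold cross-validation with strict
    training-view recomputation, leave-one-disease-out candidate ranking, a
    synthetic benchmark generator with planted block structure, and tidy
    accessors plus ggplot2 plots for all result types.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    randomForest,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    e1071
Suggests:
    ChemmineR,
    ChemmineOB,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
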