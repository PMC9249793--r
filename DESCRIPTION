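Package: enmhazard
Title: Multi-Layer Hazard Classification and Biomarker Discovery for
    Engineered Nanomaterials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for toxicogenomic hazard
    assessment of engineered nanomaterials (ENMs). Heterogeneous in vitro
    assay readouts are homogenized into ordinal toxicity scores (1-6),
    materials are grouped into ordered hazard classes (no-to-low, medium,
    high) by k-means, similarity network fusion of multiple assay views,
    or bronchoalveolar-lavage neutrophil-count thresholds; the number of
    clusters is assessed with a restart-stability analysis of spherical
    Gaussian-mixture BIC. Compact multivariate biomarker models are
    selected from omics layers by univariate screening, PCA-logistic
    regression, multinomial LASSO with nested cross-validation,
    random-forest backward elimination, and a genetic-algorithm wrapper
    with a fuzzy accuracy/size trade-off; models are ranked by a weighted
    sum of test accuracy and Dice-Sorensen selection stability, and the
    top-ranked random-forest models are ensembled to predict hazard
    classes for external expression profiles. Linear models relate
    selected markers to log-transformed neutrophil counts. A synthetic
    study generator with planted class structure makes the whole pipeline
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    glmnet,
    nnet,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
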