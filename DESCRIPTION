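Package: pairedSDM
Title: Paired-Scenario Ensemble Species Distribution Modelling with a
    Randomized Map-Validation Rubric
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for contrasting natural-only and human-disturbance
    ensemble species distribution models of Sphenomorphus incognitus on a
    common landscape: occurrence thinning, predictor collinearity
    filtering, pseudo-absence sampling, a nine-learner presence/background
    registry with TSS/AUC/Kappa/CSI evaluation and a conditional composite
    model score, top-k ensembles, permutation variable importance,
    Fisher-Jenks four-grade habitat classification with area and centroid
    change accounting, a per-point paired-map scoring rubric with a 50-km
    habitat-fragmentation criterion, and the likelihood-ratio G-test on
    the resulting tallies. Includes a seeded synthetic-landscape and
    virtual-species generator so the whole workflow is testable without
    external raster data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    nnet,
    rpart,
    randomForest,
    xgboost,
    glmnet,
    mgcv,
    geosphere,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    igraph,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
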