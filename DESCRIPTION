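Package: batseeg
Title: Predicting Brief Acoustic Tinnitus Suppression from Resting-State EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for predicting brief acoustic tinnitus
    suppression (BATS) status from resting-state EEG. Implements per-epoch
    spectral feature extraction (canonical band power, band-limited spectral
    Shannon entropy, aperiodic 1/f offset and slope), Desikan-Killiany
    source-label band power, magnitude-squared coherence aggregated over
    large-scale resting-state networks, Pearson-correlation feature merging,
    a ten-classifier benchmark with threshold sweeps and a shuffled-label
    null, and tree-ensemble explainability (impurity importance, Shapley-style
    signed contributions, partial dependence). Includes a synthetic EEG cohort
    generator with configurable planted group effects so every stage is
    testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    ranger,
    xgboost,
    MASS,
    e1071,
    rpart,
    kernlab,
    class,
    nnet,
    igraph,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
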