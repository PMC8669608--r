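Package: drughybrid
Title: Sequence-Based Prediction of Druggable Proteins with Hybrid
    Descriptors and Bagging-SVM
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds and evaluates binary classifiers of protein
    druggability from amino-acid sequence alone. Implements three
    fixed-length sequence descriptors (grouped amino-acid composition,
    cross-covariance over physicochemical property profiles, and gapped
    k-mer "monoDiKGap" composition), redundancy-aware feature selection
    (boosted-stump importance, MRMD relevance/distance ranking, and
    PageRank fusion of multiple ranker lists), and a bagging ensemble of
    support vector machines with majority voting. Includes stratified
    cross-validation and holdout evaluation, parameter sweeps, a
    synthetic labeled-sequence generator with controllable class signal,
    and a command-line interface wiring the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    class,
    e1071,
    glmnet,
    jsonlite,
    randomForest,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    igraph,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
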