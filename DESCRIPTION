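Package: cewalk
Title: circRNA-Disease Association Prediction from ceRNA Network Embeddings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds a heterogeneous competing-endogenous-RNA (ceRNA) network
    from bipartite relation sets over circRNAs, miRNAs, mRNAs and diseases,
    augments it with sequence-similarity edges between circRNAs and
    Wang-measure semantic-similarity edges between diseases, learns node
    embeddings with a from-scratch DeepWalk (skip-gram over truncated uniform
    random walks, hierarchical softmax), and trains binary classifiers on
    concatenated circRNA/disease embedding pairs to predict novel
    circRNA-disease associations. Includes a balanced negative-sampling
    benchmark builder, a five-fold cross-validation metric suite with ROC/AUC,
    an embedding-size sweep, a probability-ranked case-study predictor, and a
    synthetic-fixture generator with planted community structure so the whole
    pipeline is testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    igraph,
    Biostrings,
    e1071,
    randomForest,
    xgboost,
    nnet
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
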