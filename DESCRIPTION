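Package: hybridseq
Title: Hybrid Cluster-Routed Ensemble Classification of Gene Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies nucleotide sequences from k-mer composition using a
    five-phase hybrid model: k-mer frequency featurization, min-max scaling and
    linear discriminant projection, logistic-regression class probabilities,
    k-means clustering of the probability vectors to augment training labels
    with latent-subgroup identities, an SVM bridge that routes test samples to
    clusters, and per-cluster soft-voting ensembles over SVM, random forest,
    logistic regression, k-nearest-neighbour and multilayer-perceptron base
    learners. Includes hold-out and k-fold evaluation with confusion-matrix
    metrics, ROC and precision-recall curves, two-proportion Z and chi-squared
    classifier comparison tests, Gaussian-process Bayesian hyperparameter
    tuning, and a synthetic sequence generator with planted class and subgroup
    structure.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    caret,
    cluster,
    e1071,
    jsonlite,
    lhs,
    nnet,
    randomForest,
    stats,
    utils
Suggests:
    MASS,
    mclust,
    pROC,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
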