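Package: cloudr
Title: Classification and Parameter Prediction for Duplicate Gene Retention
    from Expression Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements the CLOUD approach to learning duplicate gene
    retention mechanisms from multi-tissue gene expression data.
    Expression evolution of a parent copy, child copy, and ancestral
    single-copy ortholog is modelled as an Ornstein-Uhlenbeck process on
    the three-gene tree, yielding closed-form means and covariances used
    to simulate labelled training data under five retention classes
    (conservation, neofunctionalization of parent or child,
    subfunctionalization, specialization). Simulated triplets are
    converted to a 4m+84 feature vector combining raw expression,
    Euclidean distances, branch lengths, Pearson correlations, and
    empirical ranks and moments against a genome-wide single-copy
    background, and fed to an elastic-net-regularized dense feed-forward
    neural network (trained with Adam) that classifies retention
    mechanisms and predicts the per-tissue evolutionary parameters
    (optimal expression states, selection strength, phenotypic drift).
    Includes simulation experiment harnesses, five-fold cross-validation
    over network depth and regularization, and an end-to-end pipeline for
    empirical expression tables and Newick gene trees.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    ape,
    pROC,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    nnet,
    withr,
    jsonlite
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
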