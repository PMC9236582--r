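Package: sitelasso
Title: Lasso-Based Site Sampling for Fast Phylogenetic Likelihood
    Approximation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Approximates the log-likelihood of a phylogenetic tree from a
    small weighted subset of alignment sites.  Per-site log-likelihoods of a
    set of random trees are used to train a positive-coefficient Lasso
    regression; the selected sites and their weights then stand in for the
    full alignment during likelihood evaluation, in particular inside a
    two-phase subtree-prune-and-regraft (SPR) hill-climbing tree search.
    Includes a native pruning-algorithm likelihood engine with discrete-gamma
    rate heterogeneity (WAG, JTT, LG, GTR), empirical-Bayes site rates,
    random and parsimony stepwise-addition starting trees, sequence
    simulation along trees, partitioned training, and an evaluation harness
    with naive site-sampling baselines.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    phangorn,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
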