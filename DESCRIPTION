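Package: panelnet
Title: Temporal Attitude Networks from Multi-Wave Mixed Questionnaire Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation and comparison of psychometric attitude networks over
    repeated questionnaire waves. Provides a Gibbs-sampling generator for
    multi-wave panels from known pairwise Markov random fields over mixed
    (binary and Gaussian) nodes, nodewise EBIC-penalized mixed graphical model
    estimation, EBIC-regularized graphical lasso partial-correlation networks,
    nonparametric bootstrap accuracy of edge weights and case-dropping
    stability of strength centrality, iterated walktrap consensus community
    detection, a permutation network comparison test (global strength,
    structure invariance, edge-wise differences), and logistic/linear trend
    models fitted by generalized estimating equations with robust covariance.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    igraph,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), knitr, rmarkdown, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
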