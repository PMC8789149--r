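Package: bdnet
Title: Bayesian Differential Network Estimation via the Adaptive Graphical Lasso
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Estimates differential networks (the difference of two Gaussian
    graphical model precision matrices) from two-condition data. Each
    precision matrix is estimated with a Bayesian adaptive graphical lasso
    block Gibbs sampler; graph structure is determined by thresholding
    posterior-mean partial correlations obtained under a conjugate Wishart
    reference posterior, with a Matthews-correlation-driven grid search for
    the threshold. Includes generators for nine benchmark precision-matrix
    structures (autoregressive, sparse random, scale-free, band, cluster,
    star, circle), loss and edge-classification metrics, and a replication
    study harness, plus nonparanormal and moving-average preprocessing for
    real data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
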