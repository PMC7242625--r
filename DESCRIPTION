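Package: cdmcluster
Title: Spectral and K-Means Clustering for Cognitive Diagnostic Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classifies examinees into attribute-homogeneous groups from
    binary test responses. Implements a spectral clustering algorithm on the
    normalized graph Laplacian of a Gaussian-kernel similarity matrix,
    K-means over attribute sum-scores with best, Ward and random starting
    values, and marginal maximum likelihood (EM) estimation of the G-DINA,
    DINA, DINO and A-CDM cognitive diagnosis models. Includes a Monte-Carlo
    simulation engine for factorial studies of classification accuracy
    (Adjusted Rand Index, within-cluster homogeneity omega, root mean
    squared within-cluster residual) and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
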