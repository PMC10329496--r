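Package: iscclust
Title: Information-Incorporated Sparse Convex Clustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sparse convex clustering with literature-informed feature
    weights for disease subtyping from multi-omics data. Sample centers are
    fused through a weighted fused-lasso penalty on k-nearest-neighbour
    sample pairs while features are selected through a group-lasso penalty
    whose per-feature weights encode prior evidence (publication
    co-occurrence counts). The objective is minimized by an alternating
    minimization algorithm (AMA, dual ascent) with exact group soft
    thresholding, and the penalty pair is tuned either against known
    cluster/feature counts or by cluster- and feature-level BIC criteria.
    Includes simulation designs with embedded confounding ("noisy")
    cluster patterns, prior-weight corruption at controlled accuracy rates,
    replicate study drivers, and clustering/selection accuracy metrics
    (adjusted Rand index, FNR, FPR, Matthews correlation coefficient).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    igraph,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    withr
Config/testthat/edition: 3
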