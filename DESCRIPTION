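Package: rhodonet
Title: Comparative Gene Co-Expression Networks, Module Preservation and
    Local Network Similarity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds signed weighted gene co-expression networks from
    condition-averaged robust z-scores using biweight midcorrelation and
    soft thresholding, detects co-expression modules by topological
    overlap clustering, and quantifies module quality and cross-dataset
    preservation with permutation Z statistics (Zsummary, medianRank).
    Computes Local Network Similarity (LNS) expression-divergence scores
    for one-to-one ortholog pairs with ortholog-map randomization nulls
    and a within-species split-half variant, hypergeometric gene-set
    over-representation with Benjamini-Hochberg correction, and a
    rank-based permutation test for differential DNA packaging of
    modules. Includes a two-species synthetic data generator with
    planted, partially preserved module structure, a proteomics-like
    layer with missing values, and full ground truth for method
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
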