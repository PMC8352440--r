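Package: pathsvm
Title: Disease-Gene Prioritization with Shortest-Path Features and a
    Least-Squares SVM
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Guilt-by-association prioritization of candidate disease
    genes. Candidate genes are collected from diseases similar to a
    target disease, featurized by weighted shortest-path (Dijkstra)
    distances to each similar disease's known gene set in a functional
    gene interaction network, and classified by a least-squares support
    vector machine with a Gaussian radial basis kernel, trained by
    solving its Karush-Kuhn-Tucker linear system. Includes k-fold
    cross-validated ROC/PR evaluation, ranking of unlabeled candidates,
    readers and writers for the tab-separated input formats
    (disease-disease similarities, disease-gene associations, weighted
    edge lists), and a planted-module synthetic benchmark generator so
    the whole pipeline can be exercised without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    optparse
Config/testthat/edition: 3
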