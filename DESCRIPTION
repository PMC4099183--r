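Package: anni
Title: Gene-Gene Interaction Network Inference with Neural Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers signed, directed gene-gene interaction networks from
    expression data by training one backpropagation multilayer perceptron
    per gene (that gene as output, all other genes as inputs) under
    Monte-Carlo cross-validation, then aggregating the trained connection
    weights into interaction scores. Includes Pearson-correlation filtering
    of candidate edges, strongest-edge-per-gene network simplification with
    hub detection, Cytoscape-compatible exports (SIF, GraphML, edge tables),
    a truncated p-value utility with Benjamini-Hochberg adjustment, and a
    synthetic expression-data generator with planted correlated blocks for
    benchmarking recovery of known correlation structure.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
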