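Package: hypermi
Title: Hypergraph Community Detection by Compression Entropy Minimization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Community detection in hypergraphs by maximizing the mutual
    information between a hypergraph and its clustered compression,
    equivalently by minimizing the microcanonical compression entropy
    log Z(gamma).  Implements simple, multiset and degree-corrected
    counting models for the number of hypergraphs compatible with a
    compression, Metropolis-Hastings simulated annealing over vertex
    label assignments, minimum description length selection of the
    number of clusters, simple and multi-edge clique projections,
    planted-partition and degree-corrected hypergraph stochastic
    blockmodel benchmark generators, adjusted Rand index scoring and a
    spectral clustering baseline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
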