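Package: reconet
Title: Structure-Preserving Replication and Scaling of Complex Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Generates realistic replicas of undirected networks at the
    original or a scaled-up size with ReCoN, a generator that randomizes
    edges within and between detected communities while preserving every
    node's internal and external degree. Includes fitting schemes that
    parametrize classical baseline generators (Erdos-Renyi,
    Barabasi-Albert, Chung-Lu, edge-switching Markov chain, R-MAT,
    hyperbolic unit-disk, BTER, LFR) from an input graph, a power-law
    exponent fit by average-degree bisection, a scalar realism-metric
    suite (Gini coefficient of the degree sequence, clustering, exact and
    effective diameter, component and community counts), synthetic test
    fixtures, and a command-line harness. Network signatures (community
    membership plus internal/external degrees) support anonymized
    sharing: a structurally similar graph can be regenerated without
    access to the original edges.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
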