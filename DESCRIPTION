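Package: multifacet
Title: Multifaceted Community Detection in Multiplex Networks via
    Empirical Null Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Community detection for directed, optionally weighted
    multiplex networks in which the null network of the modularity
    matrix is an empirical network layer (or its binary or weighted
    complement graph) rather than a random-graph expectation.  Provides
    construction of modularity matrices for the exclusion, inclusion
    and merged-multilayer modes alongside the classical configuration
    (Newman-Girvan) null, a generalized Louvain optimizer that accepts
    an arbitrary modularity matrix, per-module local modularity and
    within-module edge-overlap probabilities, normalized mutual
    information between partitions, a layer-contribution scan, a seeded
    planted-partition multiplex generator, and a layered edge-list file
    format with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
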