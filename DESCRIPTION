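Package: graphmapper
Title: Topological Graph Summaries and Pooling via the Mapper Algorithm
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Structural graph summarization for attributed networks using the
    Mapper construction from topological data analysis. A lens function maps
    nodes to a low-dimensional codomain, an overlapping cover of that codomain
    is pulled back to node sets, each preimage is split into clusters, and the
    1-skeleton of the nerve of the edge-refined cover yields a summary graph
    whose edges distinguish semantic (shared-node) from structural
    (shared-edge) relations. The same machinery provides two soft-cluster
    pooling operators for hierarchical graph classification: a fixed
    PageRank-lens interval-cover operator and a differentiable RBF-kernel
    operator, together with a minimal graph convolutional classifier,
    seeded synthetic-graph generators, and Graphviz/GraphML export of colored
    summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    methods,
    stats,
    grDevices,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
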