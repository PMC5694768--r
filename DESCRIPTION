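Package: hypercoal
Title: Coalescent Embedding of Complex Networks in Hyperbolic Space
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps undirected networks into the native two- or three-dimensional
    hyperbolic space by angular coalescence: topological edge pre-weighting
    (repulsion-attraction rules or edge betweenness centrality), nonlinear
    dimension reduction (Isomap, noncentered Isomap, Laplacian eigenmaps,
    minimum curvilinear embedding and its noncentered variant), circular or
    equidistant angular adjustment, and degree-based radial assignment.
    Includes a popularity-similarity-optimization (PSO) generative model with
    ground-truth coordinates, a HyperMap maximum-likelihood baseline embedder,
    and an evaluation suite (hyperbolic-distance correlation, concordance
    score, greedy-routing score, hyperbolic edge weighting for community
    detection, and normalized mutual information).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE, load = "source")
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    generics,
    ggplot2,
    igraph,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
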