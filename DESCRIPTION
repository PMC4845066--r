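Package: hierscale
Title: Hierarchical Topology, Scaling and Self-Organization of Brain Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for hierarchically modular networks such as
    structural connectomes. Recursively decomposes a graph into modules and
    sub-modules with Newman's leading-eigenvector spectral method, computes
    degree-conditioned topological curves (degree distribution, clustering
    coefficient, neighborhood connectivity) and centralities (betweenness,
    closeness, eigenvector), tests power-law behaviour with the Clauset
    x_min/KS/MLE/bootstrap machinery, collapses module-level curves onto a
    single master power law with one-parameter scaling, estimates level-wise
    fractal dimensions of module mass, intra- and inter-modular edges, and
    quantifies local-community-paradigm (LCP) structure. Ships deterministic
    and stochastic generators (Ravasz-Barabasi hierarchical graphs, nested
    stochastic block models, power-law samplers) so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
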