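Package: entrank
Title: Entropy-Based Centrality for Vital Node Identification in Weighted Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Identifies influential nodes in weighted directed and undirected
    networks with an entropy-based centrality: the local influence of a node
    combines the Shannon entropy of the degree distribution on its ego
    subgraph (structural entropy) with the entropy of its interaction-weight
    distribution (frequency entropy), and influence propagation to two-hop
    neighbours supplies an indirect component. Includes degree, betweenness,
    closeness and eigenvector baselines with explicit weighted/directed
    conventions, a weighted susceptible-infectious (SI) spreading simulator
    for scoring seed sets chosen by each ranking, a synthetic weighted-network
    generator, edge-list input/output, and ggplot2 visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
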