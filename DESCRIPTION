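Package: spreadrank
Title: Ranking Influential Spreaders in Networks from Spatiotemporal
    Ego-Subnetwork Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies influential spreaders (superspreaders) in undirected
    networks. Ground-truth node influence is measured by discrete-time
    susceptible-infected-recovered (SIR) Monte-Carlo simulation; training
    networks are generated by a ladder of dk-series null models (0k to 2.5k)
    that copy an empirical network's structure at increasing fidelity; each
    node is represented by a fixed-size ego-subnetwork carrying six classical
    centrality features; and a spatiotemporal scorer -- a graph convolutional
    encoder fused with a long short-term memory encoder over the subnetwork
    sequence, trained by a Kendall-gated heuristic local/global loop with a
    multilayer-perceptron head -- produces a global influence ranking.
    Includes classical centrality baselines, Kendall rank-agreement
    evaluation, multi-source spreading experiments, and synthetic-network
    generators for ablation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
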