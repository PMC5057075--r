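Package: kdconn
Title: Degree Rank-Order Disruption and Consensus Modularity for
    Functional Connectivity Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Construction of density-thresholded binary graphs from
    node-by-time series, global graph metrics with random-graph
    normalization (clustering, global efficiency, modularity,
    small-worldness), the degree rank-order disruption index k_D with
    node-deletion, random-subset and noise-robustness variants, and
    consensus community detection (multi-run Louvain with a resolution
    parameter, normalized mutual information, module-allegiance maps).
    Includes a synthetic-cohort generator with block-modular correlation
    structure and planted degree rank-order disruption so the full
    analysis is testable end to end without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
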