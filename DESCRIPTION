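Package: cortexflow
Title: Mesoscale Cortical Network Analysis with Absolute Tracer Link Weights
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for directed, weighted mesoscale connectomes
    obtained from retrograde tracer experiments. Converts fractional link
    weights (FLNe) to absolute labelled-neuron counts (LNe) and back,
    computes degree and strength distributions with likelihood-based
    distribution-family comparison, fits exponential and power-law
    weight-distance decay, decomposes the network into modules by
    minimising the two-level map-equation codelength over random-walk
    probability flow (with Louvain modularity as an independent
    comparison), classifies hubs and connectors from weighted
    participation coefficients and within-module z-scores, ranks links by
    probability flow, and traces time-evolving link shells around seed
    areas under a constant conduction velocity with per-synapse delay.
    Includes a spatially embedded synthetic-connectome generator with
    planted modules, exponential weight-distance decay and injection-site
    censoring, so every stage can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    MASS,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
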