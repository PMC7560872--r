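Package: mapperstates
Title: Metastable Community States in Microbiome Time Series via Mapper
Version: 0.1.0
Authors@R:
    person("Microbiome", "Dynamics Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies metastable community states and state transitions in
    microbial time series. Builds a compositional phase space from sample-by-
    taxon abundance tables using the square root of the Jensen-Shannon
    divergence (or the Aitchison distance), summarises its shape with the
    Mapper algorithm of topological data analysis, estimates per-vertex data
    density with a k-nearest-neighbour estimator, partitions the Mapper graph
    into basins of attraction around local density maxima, computes weighted
    temporal correlation functions of state occupancy, and tests robustness
    of the inferred structure under rarefaction. Includes synthetic community
    generators (an antagonistic two-species toy ecosystem and a Markov-
    Dirichlet multi-state simulator) so the full pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
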