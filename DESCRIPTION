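Package: ppitopo
Title: Topology Analysis of Protein-Protein Interaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds and analyzes protein-protein interaction (PPI) networks
    grown from a disease-associated candidate gene list and a confidence-scored
    interaction table (STRING-style). Implements the full hub/bottleneck
    workflow: extended first-neighbor network construction, giant-component
    extraction, node centralities (degree, Brandes betweenness, closeness),
    whole-network statistics, high-betweenness backbone extraction, the
    shortest-path subnetwork spanned by the candidate genes, and a
    seed-resampling validation of backbone robustness. Ships a
    preferential-attachment synthetic network generator with planted
    bottleneck nodes so every stage is testable without database downloads,
    plus readers and writers for SIF and STRING-style TSV edge lists.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    withr,
    stats,
    utils
Suggests:
    optparse,
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
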