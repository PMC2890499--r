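Package: hfnet
Title: Biomarker-Seeded Protein Interaction Network Analysis for Heart Failure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assembly and structural analysis of biomarker-seeded protein-protein
    interaction networks, motivated by heart-failure biomarker discovery. Builds a
    seed-centred interaction network from edge-list exports of curated interaction
    databases, decomposes it into a core network and islands, computes degree and
    traffic (betweenness centrality) statistics with power-law degree fitting,
    detects functional modules by greedy modularity maximization, profiles modules
    structurally and by gene-set overrepresentation (two-tailed Fisher exact tests
    with Benjamini-Hochberg correction), combines per-source candidate rankings by
    order statistics, contrasts biomarker centrality against the network background,
    and evaluates expression-based patient classification with a linear support
    vector machine under leave-one-out cross-validation. A synthetic-data module
    generates planted-partition networks with hub biomarkers, power-law graphs,
    module-aligned term maps, per-source rankings and two-class expression matrices
    so that every pipeline stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    yaml,
    jsonlite,
    mclust
Config/testthat/edition: 3
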