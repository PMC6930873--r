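Package: netpharm
Title: Network-Pharmacology Screening of Drug Targets in Protein
    Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An offline network-pharmacology pipeline for prioritising the
    protein targets through which a compound may act on a disease. Drug and
    disease target lists are expanded to their first-neighbour subnetworks in
    a background protein-protein interaction (PPI) interactome, the two
    subnetworks are merged by intersection, and the shared nodes are screened
    in two stages on degree, betweenness and closeness centrality using
    median-based cut-offs (hubs: degree more than twice the network median;
    key targets: all three centralities strictly above their cuts). Key
    targets are then tested for gene-set over-representation with an exact
    hypergeometric (or EASE) tail and Benjamini-Hochberg adjustment, with
    rich-factor scoring and top-N reporting. A seed-reproducible synthetic
    scenario generator (scale-free interactome, planted hubs, planted
    enriched gene set) makes every stage testable without any database
    access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
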