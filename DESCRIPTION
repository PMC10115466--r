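Package: ppibridge
Title: Bridge Protein-Pair Prioritization in Two-Cell Protein Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Prioritizes "bridge" protein pairs that mediate communication
    between two interacting cell types. Each cell's intracellular
    protein-protein interaction network is collapsed into per-contact-protein
    intracellular importance scores (IIS) combining PageRank centrality with
    breadth-first-search distances on two pruned networks; an exact
    branch-and-bound optimizer then solves an integer program selecting the
    cheapest set of intercellular contact-protein pairs covering at least an
    alpha fraction of the intercellular interactions. Includes pair-level
    overall importance scores (OIS), a random-selection baseline for
    annotation-enrichment evaluation, a synthetic two-cell interactome
    generator, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
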