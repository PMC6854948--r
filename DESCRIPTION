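Package: stonenet
Title: Disease-Module Analysis of Protein-Protein Interaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Assemble candidate disease-protein sets from proteomics and
    text-mining sources, map them onto a protein-protein interaction (PPI)
    interactome, build the induced disease subnetwork, test its connectivity
    against a node-sampling permutation null, extract a centrality-ranked hub
    backbone (node degree, Brandes betweenness, edge betweenness), and run
    DAVID-style hypergeometric/EASE over-representation analysis with
    Benjamini-Hochberg correction. Includes a synthetic-data generator with
    planted ground truth (scale-free interactomes, planted candidate modules,
    planted enriched annotation terms) so every pipeline stage is testable
    without external databases, plus readers and writers for TSV/SIF/GraphML
    networks and GMT gene-set files.
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
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    fgsea,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
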