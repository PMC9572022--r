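Package: coagkg
Title: Knowledge-Graph and Pathway-Crosstalk Analysis of Heme Effects on
    Blood Coagulation
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for curating and analysing knowledge graphs of
    heme-triggered effects on the blood coagulation system. Parses a
    subset of the Biological Expression Language (BEL) with
    experimental-context annotations (dose, route, cell type, binding
    affinity), compiles statements into an evidence-carrying typed
    multigraph, merges graphs, ingests harmonized pathway exports (TSV
    edge lists and GMT gene sets) from KEGG, Reactome and WikiPathways,
    stratifies proteins into extracellular, membrane and intracellular
    compartments from GO cellular-component annotations, and
    superimposes knowledge graph and pathway networks to identify common
    nodes, knowledge gaps and hypergeometric overlap significance. A
    seeded synthetic-data generator emulates all input classes with
    planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
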