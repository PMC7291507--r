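Package: bilevelppi
Title: Bi-Level Regulated Proteins and Interolog Interaction Networks from
    Temperature-Stress Proteomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for three-condition (cold / optimal / heat)
    label-free quantitative proteome and phosphoproteome experiments in
    cyanobacteria. Filters intensities against a noise threshold, calls
    differential expression between stress and optimal conditions, parses
    phosphopeptide evidence with lowercase-residue site marks, aggregates
    per-protein phosphosite inventories, intersects both layers into a
    bi-level regulated protein report, infers protein-protein interactions
    in the query species by transferring a template bait-prey network
    through reciprocal-best-hit orthology and Markov clustering, and
    renders the condition-annotated network as SVG, GraphML or SIF. A
    synthetic-data generator with planted ground truth makes every stage
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    ape,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
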