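Package: netpharm
Title: Seed-Anchored Drug-Target Network Analysis for Tumour Subgroups
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A systems-pharmacogenomics pipeline that starts from a list of
    candidate cancer genes recovered by an insertional-mutagenesis screen,
    maps them to human orthologs, anchors a protein-protein interaction
    network on them, grafts known drug-target interactions onto the network,
    overlays per-subgroup differential expression versus normal tissue
    (empirical-Bayes moderated t-statistics with Benjamini-Hochberg false
    discovery rate control), and extracts druggable over-expressed proteins
    and bridging nodes shared by all tumour subgroups. Includes a synthetic
    data generator with planted ground truth for end-to-end validation, and
    writers for Cytoscape-importable SIF and GraphML network formats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
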