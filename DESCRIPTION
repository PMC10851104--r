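Package: histonet
Title: Histone and Nucleosome Interaction Network Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds and analyzes multi-granularity histone/nucleosome
    interaction networks from macromolecular structures. Extracts
    residue-level binding interfaces from heavy-atom contacts at a
    configurable distance cutoff, classifies them into histone-histone,
    histone-DNA, histone-partner and DNA-partner interactions (including
    contacts at post-translationally modified sites), assembles residue-,
    domain- and protein-level networks from structural and external
    evidence, computes Maximal Clique Centrality and other topological
    metrics for hub detection, characterizes nucleosome-partner binding
    modes and binding hotspots on the histone octamer and nucleosomal DNA,
    and maps cancer-associated histone mutations onto binding interfaces
    with physicochemical profiling and pluggable binding free energy change
    prediction. Includes seeded synthetic-data generators with planted
    ground truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    igraph,
    jsonlite,
    yaml,
    Biostrings,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
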