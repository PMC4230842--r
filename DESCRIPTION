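Package: cometh
Title: Comparative Methylome Segmentation and Differential Methylation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of whole-genome bisulfite sequencing data across
    related plant species: methylation calling from per-cytosine count
    tables with spike-in based conversion-failure estimation, segmentation
    of methylomes into methylated regions with a two-state hidden Markov
    model using context-specific beta-binomial emissions, differential
    methylation testing at single positions (Fisher's exact test) and at
    regions (beta-binomial log-odds test with Storey q-values), cross-species
    classification of aligned cytosines into conservation classes, overlap
    statistics at orthologous genes, and negative-binomial differential
    expression with analysis-of-deviance term tests. Includes simulators
    for every input format so the full pipeline can be exercised against
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    MASS,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
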