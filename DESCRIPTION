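Package: TEreg
Title: Regulatory Signatures of Transposable Element Families
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies transposable-element (TE) families with gene-regulatory
    signatures from epigenomic peak data. Implements per-family peak enrichment
    against a permutation null of length-preserving shuffled peaks that avoid
    unmappable regions, multi-assay candidate-family selection (concordant
    histone-acetylation enrichment across cell contexts plus open-chromatin
    tissue specificity), chromatin-state combination profiling of family
    copies, distance-stratified association between marked elements and gene
    expression changes, TE-derived promoter detection, and cross-species
    comparison of expression near shared versus species-specific elements via
    reciprocal coordinate mapping. A seeded synthetic-data module generates
    genomes, annotations, peaks, expression and two-species fixtures with
    planted structure for validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    withr,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
biocViews: Epigenetics, FunctionalGenomics, GeneRegulation, Transcription,
    Software
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
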