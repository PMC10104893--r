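Package: chronoremodel
Title: Diurnal Rhythm Detection and Cross-Genotype Rhythm Remodeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Nonparametric detection of diurnal (~24 h) rhythms in time-course
    omics data using a JTK_CYCLE-style test with exact Kendall-S null
    distributions, including series duplication for short sampling designs,
    RPKTM normalization and expression filtering, quantile normalization for
    lipidomics, identification of intergenic enhancer loci from ATAC peaks with
    eRNA quantification in fixed windows, and cross-genotype classification of
    rhythm remodeling (lost, gained, shared, restored). Ships a synthetic-data
    generator with planted ground truth for end-to-end validation of the three
    pipelines (transcripts, enhancers, lipids).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    jsonlite,
    yaml,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr
Config/testthat/edition: 3
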