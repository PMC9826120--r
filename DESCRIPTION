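Package: methylTSD
Title: Sex- and Temperature-Associated DNA Methylation Analysis for
    Species with Temperature-Dependent Sex Determination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of reduced-representation bisulphite sequencing (RRBS)
    methylation calls for studies of temperature-dependent sex determination.
    Reads bismark-style coverage files into a locus-by-sample count container,
    applies methylKit-style coverage and invariance filters, tests each CpG
    for sex- or temperature-associated differential methylation with an
    overdispersion-corrected binomial logistic regression, classifies
    differentially methylated cytosines with sex-precedence, annotates loci
    by gene context, predicted CpG islands/shores/shelves and local CpG
    density, scans for hormone-response elements with position weight
    matrices, builds sparse elastic-net predictors of hatchling sex and past
    incubation temperature, and ships a beta-binomial simulator of the whole
    study design for end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    Biostrings,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
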