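Package: GBMprofiler
Title: Genomic and Transcriptomic Profiling of Treatment Response in
    Glioblastoma
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for studying treatment response in
    glioblastoma from array-CGH and expression microarray data. Implements
    purity-aware five-state copy-number calling on BAC-clone log2 ratios
    (exact least-squares segmentation, mode/MAD thresholds, tumor-cell-rate
    based homozygous-deletion and amplicon detection), minimal common region
    derivation, differential-genomics testing with Fisher exact tests and
    Benjamini-Hochberg adjustment, nearest-centroid tumor subtyping,
    empirical-Bayes moderated t differential expression, hypergeometric
    gene-set over-representation, and Kaplan-Meier / log-rank survival
    statistics. A fully parameterized synthetic-cohort generator emulating a
    two-arm (radiotherapy / chemotherapy) responder study makes every stage
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    yaml,
    optparse
biocViews: CopyNumberVariation, GeneExpression, Classification, Survival
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'GBMprofiler-package.R'
    'AllGenerics.R'
    'AllClasses.R'
    'association.R'
    'calling.R'
    'expression.R'
    'io.R'
    'mcr.R'
    'pipeline.R'
    'segment.R'
    'simulate.R'
    'stats.R'
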