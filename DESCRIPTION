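Package: exonsplice
Title: Exon-Level Alternative Splicing Statistics for Exon Arrays
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis of Affymetrix-style exon array datasets downstream of
    probeset summarization. Provides transcript-cluster normalization, the
    Splicing Index, Student's t and ANOVA (MiDAS-style) statistics for
    alternative splicing detection, DABG detection filtering, isoform-filtered
    gene-level summarization and differential expression, per-gene meta
    statistics with scaled Euclidean-distance gene ranking, and a
    conditional-inference decision tree relating exon expression to clinical
    covariates. Includes a synthetic exon-array simulator with planted
    cassette-exon and mutually-exclusive-exon events for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: AlternativeSplicing, Microarray, ExonArray, DifferentialSplicing,
    DifferentialExpression, Software
RoxygenNote: 7.3.3
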