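Package: footprintr
Title: In-Silico Genomic Footprinting of Promoters of Drug-Regulated Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for in-silico genomic footprinting of gene promoters:
    position weight matrix (PWM) construction from aligned binding-site
    collections, MATCH-style matrix/core similarity scanning, strand-aware
    promoter extraction around transcription start sites, foreground versus
    background binding-site density enrichment, composite cis-regulatory
    module discovery around anchor sites, a differential-expression stage
    (fold-change and FDR selection, Venn partitioning, fold-change
    histograms, average-linkage clustering on uncentered correlation,
    delta-delta-Ct quantification, hypergeometric over-representation),
    body-surface-area dose translation and balanced one-way ANOVA power
    calculators, and a synthetic-data generator with recorded ground truth
    for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
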