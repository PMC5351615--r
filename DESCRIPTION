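Package: dmfscreen
Title: Fragment-Based RRBS Differential Methylation and Epigenetic Driver Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reduced representation bisulfite sequencing (RRBS)
    analysis using in-silico MspI restriction fragments as the unit of
    differential methylation. Implements genome digestion into a fragment
    catalog, Bismark-style coverage ingestion with replicate merging and
    coverage filtering, per-pair differentially methylated fragment (DMF)
    calling by two-sided Fisher's exact test with Bonferroni correction and a
    25 percent mean-difference threshold, a cross-pair shared-DMF screen for
    candidate epigenetic drivers of metastasis (direction consistency,
    progression patterns, CpG island/shore and gene-context annotation), and
    validation statistics (Pearson and Bland-Altman platform concordance,
    Mann-Whitney cohort tests, Spearman methylation-expression correlation).
    A synthetic-data module simulates genomes, methylation states with planted
    DMFs, beta-binomial read counts, array-style cohort beta matrices and
    expression tables with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    ape,
    yaml,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
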