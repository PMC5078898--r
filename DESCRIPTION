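Package: dipseqr
Title: Enriched-Domain Segmentation and Differential Methylation Analysis
    for DIP-Seq with RNA-Seq Integration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for methylated and hydroxymethylated DNA
    immunoprecipitation sequencing (meDIP/hmeDIP, "DIP-Seq") analysis:
    sliding-window enrichment segmentation against a Monte-Carlo permutation
    background with window-size optimization, merged-region differential
    methylation calling (chi-square on pooled counts or a replicate-aware
    negative-binomial Wald test) with FDR and tag-difference filters,
    negative-binomial differential expression with median-of-ratios size
    factors and Storey q-values, DMR-to-gene TSS annotation, top-N
    methylation/expression overlap statistics, expression-sorted meta-gene
    density matrices with intragenic-difference ranking, and generic
    Fisher/Wallenius/KS gene-set enrichment with length-bias correction.
    Includes a synthetic-data generator with planted enriched domains,
    differentially methylated regions, differentially expressed genes and
    methylation-expression coupling, plus truth tables for recovery scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    data.table,
    rtracklayer,
    stats,
    utils,
    yaml
Suggests:
    DESeq2,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
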