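Package: glueSelect
Title: Lineage-Selective Drug Response and Splicing Concordance Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for identifying cancer-lineage-selective compounds in pooled
    viability screens and for quantifying the concordance between genetic and
    pharmacologic perturbation of a splicing factor. Implements a target-vs-rest
    mean-difference statistic with a Monte-Carlo or exhaustive permutation null
    and add-one empirical p-values; lineage comparison of gene-dependency scores;
    construction of unified splice-junction read matrices from STAR SJ.out.tab
    files with counts-per-million normalization, genotype averaging, low-count
    filtering and pairwise Pearson correlation; post-processing of rMATS
    differential-splicing tables (significance filtering, per-category counts,
    cross-comparison overlap and delta-PSI rank correlation); and fully
    deterministic synthetic-data generators with ground-truth ledgers so the
    entire pipeline runs and is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
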