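Package: clipwalk
Title: iCLIP Occupancy Ranking, Walk-Down Target Thresholds, and
    Genotype-by-Treatment Interaction Models for RBP Regulomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for inferring the mRNA target set (regulome) of an
    RNA-binding protein from iCLIP crosslink data together with bulk
    RNA-seq. Implements random-barcode PCR deduplication of iCLIP tags,
    genomic segment classification under a fixed priority hierarchy,
    permutation-FDR crosslink cluster calling with 31-nt occupancy
    windows, expression-normalized occupancy scoring and wildtype-minus-
    null gene ranking, pentamer z-score motif enrichment against
    composition-preserving shuffled controls, walk-down functional
    annotation threshold estimation with permuted-ranking controls and
    piecewise-linear inflection detection, per-gene genotype-by-treatment
    interaction ANOVA on rank-based normal scores with a pooled
    permutation null, enrichment-direction contingency analyses, and
    2^ddCt qPCR fold changes. A synthetic-data module generates
    annotation, sequences, crosslink tags, count matrices, and term sets
    with the statistical structure the analysis assumes, so the whole
    chain is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    BiocGenerics,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
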