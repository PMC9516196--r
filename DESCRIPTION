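Package: mutmapr
Title: Bulked-Segregant SNP-Index Mapping and Co-Regulation Analysis for
    Rice Mutant Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to map recessive causal mutations from pooled F2
    sequencing by the MutMap bulked-segregant strategy (quality filtering,
    shared-SNP and cross-pool exclusion, SNP-index genome scans and peak
    calling), to classify candidate SNPs by codon consequence against gene
    models, to test Mendelian segregation ratios with and without the Yates
    continuity correction, to summarise multi-contrast differential
    expression overlap and direction concordance, and to test ontology-term
    enrichment with an empirical permutation correction. A forward simulator
    of mutagenized lines, F2 mutant pools, differential-expression tables
    and term annotations with known ground truth makes every stage testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    Matrix,
    methods,
    rtracklayer,
    S4Vectors,
    stats,
    utils,
    vcfR,
    withr
Suggests:
    jsonlite,
    pheatmap,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
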