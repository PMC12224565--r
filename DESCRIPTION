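Package: poolsweep
Title: Selection-Signature Scans from Pool-Sequencing Allele Depths
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects selective sweeps from DNA-pool sequencing data. Estimates
    per-SNP fixation index (FST) between pools from reference/alternative read
    depths with the Karlsson unbiased allele-count estimator, computes pooled
    heterozygosity (Hp) and mean FST in non-overlapping genomic windows,
    selects empirical-percentile outlier windows, merges and extends candidate
    sweep regions, classifies and prioritises variants against gene models,
    summarises population structure (pairwise-FST distance matrix, UPGMA
    clustering, principal coordinates), and tests sweep-region gene lists for
    term enrichment with Fisher's exact test and Benjamini-Hochberg
    correction. Includes a deterministic synthetic pool-sequencing generator
    with planted sweep regions for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    ape,
    vcfR,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
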