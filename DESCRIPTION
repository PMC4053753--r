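Package: helpdmr
Title: Differential Cytosine Methylation Analysis for HELP Two-Channel Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Processing and downstream analysis of HELP (HpaII tiny fragment
    Enrichment by Ligation-mediated PCR) two-channel methylation microarrays.
    Summarizes probe-level HpaII/MspI intensities into per-fragment signals,
    flags failed and fully methylated loci against a random-probe background,
    applies intra-array sliding-window quantile normalization over
    size-sorted HpaII-amplifiable fragments, and tests centered
    log2(HpaII/MspI) ratios for case-control differences. Differentially
    methylated regions (DMRs) are placed in genomic context (RefSeq-style
    categories, chromatin-state segmentations, DNase hypersensitive sites
    with matched-random-locus permutation tests) and integrated with gene
    expression, replication-platform methylation differences and absolute
    methylation measurements. A synthetic-data generator with known planted
    truth makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    data.table,
    jsonlite,
    yaml,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
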