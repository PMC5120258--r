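Package: fbsmeth
Title: Frequently Bivalent Chromatin Segments and DNA Methylation in Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing bivalent chromatin (H3K4me3 + H3K27me3) in
    cancer from ChromHMM-style 15-state segmentations and 450k-style DNA
    methylation beta values. Builds frequently bivalent segments (FBS) by
    merging bivalent intervals across many cell-type segmentations with
    distinct-contributor counting, scores samples with a training-free
    relative-methylation cancer classifier evaluated by ROC/AUC, quantifies
    chromatin-category stability between paired segmentations, profiles
    methylation differences within and around segments, classifies the fate of
    bivalent regions (stable/lost/new) in cancer, and integrates methylation
    change with differential-expression results via quadrant statistics.
    Includes a seeded synthetic-data generator emulating segmentations, beta
    matrices with purity mixing, and differential-expression tables so every
    stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
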