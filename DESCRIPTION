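Package: liquidmeth
Title: Tumor-Informative Methylation Analysis of Cell-Free DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Discovery and clinical use of tumor-derived DNA methylation
    signals in plasma cell-free DNA profiled by methylated-DNA
    immunoprecipitation sequencing (cfMeDIP-seq). Counts fragments into a
    fixed genome-wide window universe, suppresses the hematopoietic
    methylation background by combining cell-type whole-genome bisulfite
    beta values into a weighted exclusion mask, calls differentially
    methylated regions between patient and healthy-donor cfDNA with TMM
    normalization and an empirical-Bayes moderated t-statistic, validates
    them against tissue by a permutation overlap test, summarizes them
    into a per-sample 5-mC score with a max-of-healthy detection
    threshold, tracks longitudinal therapy response with a nadir-based
    molecular-progression rule, and estimates chromosomal instability as
    a trimmed median absolute deviation (t-MAD) of panel-normalized 1-Mb
    log2 copy-number ratios. A synthetic-data generator reproduces the
    statistical structure the analysis assumes, with ground truth for
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    edgeR,
    limma,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
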