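Package: methdelay
Title: Differential Methylation, Bivalent-Domain Enrichment, and
    Developmental-Delay Trajectory Analysis for Methylation Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for case/control analysis of CpG methylation
    beta-value matrices from genome-wide arrays: probe filtering by
    detection quality, missingness and SNP overlap; differential
    methylation calling with a moderated t-statistic (empirical-Bayes
    variance shrinkage) and a label-permutation null; genomic-region and
    bivalent chromatin-domain enrichment via an exact interval engine;
    definition of epigenetically dynamic regions (bivalent domains with
    developmentally dynamic methylation); correlation of postnatal group
    methylation profiles against stage-binned fetal reference methylomes
    to score epigenetic delay; methylation-based cell-type concordance;
    and a seeded synthetic-data generator with planted ground truth so
    the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
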