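Package: incompatscan
Title: Transcriptional Response Analysis for Fungal Heterokaryon
    Incompatibility Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for time-course expression data from fungal
    heterokaryon incompatibility experiments (self-incompatible strain versus
    wild-type control). Provides moderated t-statistics with empirical-Bayes
    variance shrinkage and false-discovery-rate control, signed fold-change
    regulation calls including incompatibility-specific and silenced genes,
    robust expression-profile clustering by intersection of UPGMA and k-means
    partitions, two-tailed Fisher exact enrichment of annotation categories,
    a run-length null model for clusters of adjacent coregulated genes with
    Monte-Carlo validation, chromosome-level enrichment, sliding-window
    density scans, cross-species ortholog overlap statistics, and a
    synthetic-data generator with planted ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr
Config/testthat/edition: 3
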