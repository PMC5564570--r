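Package: rmodm
Title: Individualized Differential Methylation Analysis via Relative
    Methylation Orderings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Calls differentially methylated CpG sites in single cancer
    samples by exploiting the high stability of within-sample relative
    methylation orderings (RMOs) of CpG pairs in normal tissue. Stable
    ordered CpG pairs are mined from pooled normal methylation profiles;
    in each cancer sample, reversals of these orderings around a
    candidate site are tallied and an asymmetry between
    reversals-supporting-hypermethylation and
    reversals-supporting-hypomethylation is tested with Fisher's exact
    test (the RankComp scheme), with per-sample Benjamini-Hochberg
    control. Includes population-level candidate screening from two
    cohorts, precision evaluation against paired adjacent normal tissue,
    promoter-level gene aggregation with cross-sample frequency
    classification, per-sample hypergeometric pathway enrichment, and a
    synthetic methylation-cohort generator with full ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
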