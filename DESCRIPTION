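Package: urotrace
Title: Longitudinal Mutant-DNA Monitoring in Plasma and Urine Liquid Biopsies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for tracking tumour-derived mutant DNA (mutDNA) in plasma and
    urine of muscle-invasive bladder cancer patients during neoadjuvant
    chemotherapy. Implements shallow whole-genome copy-number profiling from
    binned read counts (GC/mappability correction, circular binary segmentation,
    robust gain/loss calling), a genome-wide imbalance score against a pooled
    germline control, pairwise profile concordance via adjusted R-squared, a
    dual-threshold mutant allele-fraction detection rule (technical floor and
    per-reaction genomic-equivalents floor), and the outcome layer: recurrence
    prediction contingency metrics with exact binomial confidence intervals,
    Kaplan-Meier and log-rank analysis, and group comparison tests. A synthetic
    cohort generator with clonal copy-number and SNV ground truth makes every
    stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
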