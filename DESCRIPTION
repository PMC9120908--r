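Package: mfastseqr
Title: Genome-Wide Aneuploidy Scoring from mFast-SeqS Cell-Free DNA Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the mFast-SeqS (modified Fast Aneuploidy Screening
    Test-Sequencing System) analysis of cell-free DNA: binning of LINE-1
    amplicon alignments into chromosome-arm read counts, reference-panel
    normalization, per-arm Z-scores and a genome-wide aneuploidy score with
    a high/low call, plasma variant-detection filtering, arm-level
    tissue-plasma copy-number concordance, and the clinical association
    stage (predictive metrics, chi-square, Kaplan-Meier/log-rank, uni- and
    multivariate logistic regression with repeated cross-validation).
    Includes a synthetic-data generator for healthy panels, aneuploid cfDNA
    mixtures at a given tumor fraction, plasma variant tables, copy-number
    segment tables and clinical cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rsamtools,
    survival,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
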