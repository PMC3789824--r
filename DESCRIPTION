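Package: cnvburden
Title: Rare and De Novo Copy-Number-Variant Burden Analysis for
    Case-Control Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for rare copy-number-variant (CNV)
    case-control analysis in disease cohorts genotyped on SNP arrays:
    parsing of PennCNV-style call lists, sample- and call-level quality
    filtering, adjacent-call merging, identification of rare CNVs by
    per-gene carrier frequency, a stratified genome-wide burden scan with
    exact tests and Bonferroni correction, per-gene association tests with
    Benjamini-Hochberg control, selection of patient-specific CNVs by a
    gene-sharing criterion, additive pathogenicity scoring, gene-based
    overlap with reference de novo CNV sets, qPCR delta-delta-Ct copy-state
    and inheritance calling, and exact achieved power of the Fisher test
    for two independent proportions.  A synthetic-cohort generator with
    ground-truth records supports calibration and recovery testing.
License: MIT
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
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
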