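Package: cardioTriage
Title: Rule-Based Rare-Variant Triage for Cardiomyopathy Gene-Panel Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Phenotype-aware triage of rare variants from targeted
    cardiomyopathy gene-panel sequencing. Applies phenotype-specific
    minor-allele-frequency and read-support inclusion criteria, then a
    multi-rule pathogenicity engine combining in-silico predictor consensus
    (SIFT, PROVEAN, PolyPhen-2, MutationTaster), a MutationTaster-only rule
    for radical variants (stop-gain, stop-loss, canonical splice,
    insertion/deletion), titin (TTN) isoform-aware A-band rules for
    truncating variants, and ClinVar/HGMD/literature evidence overrides and
    demotions. Cohort-level analytics cover per-patient variant burden,
    per-gene tallies, phenotype-overlap partitions and detection of novel
    gene-phenotype associations against a panel catalog. A seeded synthetic
    cohort simulator with recorded ground truth makes every stage testable
    without access to controlled sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
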