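Package: sexbiome
Title: Cross-Cohort Sex-Association Meta-Analysis of Gut Metagenomes and
    Positional Antigen-Mimicry Scanning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for identifying sex-associated gut bacterial
    species across many shotgun-metagenomic cohorts and following them into
    an independent case-control cohort.  Samples pass quality-control
    filters and covariate binning; relative abundances are centred log-ratio
    (CLR) transformed; per-species sex effects are estimated with a linear
    mixed model carrying a study random intercept (abundance) and a
    fixed-effects logistic model (prevalence); Benjamini-Hochberg FDR and a
    quintile rule on effect size and significance yield a high-confidence
    species set, which is validated against disease status and clinical
    severity with likelihood-ratio tests and a 2x2 exact enrichment test.
    A positional epitope-mimicry scanner searches protein FASTA files for
    windows matching an anchor peptide at required residue positions.
    Synthetic multi-study cohorts, validation cohorts and proteomes with
    planted ground truth make every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
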