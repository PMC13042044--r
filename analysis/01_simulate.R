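#!/usr/bin/env Rscript
# Generate the synthetic study inputs with known ground truth:
#  - a multi-study discovery cohort (8 studies x 100 stool samples,
#    200 species, 20 carrying a one-log-unit sex effect),
#  - a case-control validation cohort at the emulated scale (576/576)
#    with disease and severity effects planted on five species,
#  - a bacterial proteome with 13 planted positional mimicry motifs.
suppressPackageStartupMessages(library(sexbiome))

seed <- 1L
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

spec <- synthetic_cohort_spec(seed = seed)
gen <- generate_meta_cohorts(spec)
write_cohort(gen$cohort, file.path(out, "discovery"))
write_truth(gen$truth, file.path(out, "discovery_truth.tsv"))
message(sprintf("discovery cohort: %d species x %d samples, %d planted",
                nrow(gen$cohort$abundance), ncol(gen$cohort$abundance),
                sum(gen$truth$true_direction != "none")))

planted_val <- c("sp010", "sp020", "sp030", "sp040", "sp050")
vc <- generate_validation_cohort(
  576, 576,
  disease_effects = setNames(rep(1.0, 5), planted_val),
  severity_effects = setNames(rep(0.5, 5), planted_val),
  seed = seed + 200L, n_species = 100)
write_cohort(vc, file.path(out, "validation"))
message(sprintf("validation cohort: %d cases / %d controls",
                sum(vc$metadata$disease == "MS"),
                sum(vc$metadata$disease != "MS")))

prot <- generate_proteome(100, c(60, 300), "YRSPFSRVV", c(2, 5, 7, 8),
                          n_planted = 13, seed = seed + 31L,
                          fasta = file.path(out, "proteome.faa"))
write_truth(prot$truth, file.path(out, "proteome_truth.tsv"))
message(sprintf("proteome: %d proteins, %d planted motifs written to %s",
                nrow(prot$truth), sum(prot$truth$planted), prot$fasta))

jsonlite::write_json(list(seed = seed, out = out),
                     file.path(out, "manifest.json"), auto_unbox = TRUE)
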