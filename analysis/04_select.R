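#!/usr/bin/env Rscript
# Derive the significant, high-confidence (top effect-size quintile and
# bottom FDR quintile) and cross-model-consistent species sets, and
# compare them with the planted ground truth.
suppressPackageStartupMessages(library(sexbiome))

records <- rbind(read.delim("results/assoc/associations_abundance.tsv"),
                 read.delim("results/assoc/associations_prevalence.tsv"))
truth <- read_truth("results/data/discovery_truth.tsv")

criteria <- selection_criteria()
sig <- select_significant(records, criteria)
hc <- select_high_confidence(records, criteria)
counts <- intersect_models(hc)

dir.create("results/selection", showWarnings = FALSE, recursive = TRUE)
write.table(hc, "results/selection/high_confidence.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(counts, "results/selection/intersection_counts.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

planted <- truth$species_id[truth$true_direction != "none"]
summary <- list(
  significant_abundance = sum(sig$model == "abundance"),
  significant_prevalence = sum(sig$model == "prevalence"),
  significant_union = length(unique(sig$species_id)),
  high_confidence = nrow(hc),
  consistent_both = sum(hc$consistent_both),
  hc_species_planted = sum(hc$species_id %in% planted),
  significant_planted = sum(unique(sig$species_id) %in% planted))
jsonlite::write_json(summary, "results/selection/summary.json",
                     auto_unbox = TRUE)
message(sprintf(
  "significant: %d abundance / %d prevalence (%d distinct, %d planted)",
  summary$significant_abundance, summary$significant_prevalence,
  summary$significant_union, summary$significant_planted))
message(sprintf(
  "high-confidence: %d (of which %d planted); consistent in both: %d",
  summary$high_confidence, summary$hc_species_planted,
  summary$consistent_both))
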