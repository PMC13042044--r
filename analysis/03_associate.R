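#!/usr/bin/env Rscript
# Per-species sex association: CLR transform, the abundance linear mixed
# model (study random intercept) and the prevalence logistic model, then
# Benjamini-Hochberg FDR within each model family.  Writes one results
# table per model plus a long-format export ready for volcano plotting.
suppressPackageStartupMessages(library(sexbiome))

cohort <- read_cohort("results/data/discovery")
profiles <- read.delim("results/qc/covariate_profiles.tsv")
ab <- cohort$abundance[, profiles$sample_id, drop = FALSE]

clr <- clr_transform(ab)
records <- adjust_fdr(rbind(
  fit_abundance_model(clr, profiles, detected = ab > 0),
  fit_prevalence_model(ab, profiles)))

dir.create("results/assoc", showWarnings = FALSE, recursive = TRUE)
for (m in c("abundance", "prevalence")) {
  rm_ <- records[records$model == m, ]
  write.table(rm_, sprintf("results/assoc/associations_%s.tsv", m),
              sep = "\t", quote = FALSE, row.names = FALSE)
  message(sprintf("%s model: %d fit, %d skipped, %d failed; %d at FDR<0.05",
                  m, sum(rm_$fit_status == "ok"),
                  sum(rm_$fit_status == "skipped_low_prevalence"),
                  sum(rm_$fit_status == "failed_convergence"),
                  sum(rm_$q_value < 0.05, na.rm = TRUE)))
}

volcano <- records[records$fit_status == "ok",
                   c("species_id", "model", "beta_sex", "q_value",
                     "direction")]
volcano$neg_log10_q <- -log10(volcano$q_value)
write.table(volcano, "results/assoc/volcano_long.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
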