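#!/usr/bin/env Rscript
# Follow the candidate species into the case-control validation cohort:
# disease-status and EDSS-severity linear models with likelihood-ratio
# tests, then a set-level 2x2 exact enrichment test of planted membership
# against disease significance.
suppressPackageStartupMessages(library(sexbiome))

vc <- read_cohort("results/data/validation")
candidates <- rownames(vc$abundance)

dm <- fit_disease_model(vc, candidates)
sv <- fit_severity_model(vc, candidates)
res <- rbind(dm, sv)
dir.create("results/validation", showWarnings = FALSE, recursive = TRUE)
write.table(res, "results/validation/validation.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

message(sprintf("disease model: %d/%d tested, %d at FDR<0.05",
                sum(dm$status == "tested"), nrow(dm),
                sum(dm$q_value < 0.05, na.rm = TRUE)))
message(sprintf("severity model: %d/%d tested, %d at FDR<0.05",
                sum(sv$status == "tested"), nrow(sv),
                sum(sv$q_value < 0.05, na.rm = TRUE)))

# planted membership vs disease significance
planted_val <- c("sp010", "sp020", "sp030", "sp040", "sp050")
sig <- !is.na(dm$q_value) & dm$q_value < 0.05
pl <- dm$species_id %in% planted_val
tab <- matrix(c(sum(sig & pl), sum(sig & !pl),
                sum(!sig & pl), sum(!sig & !pl)), 2, byrow = TRUE)
fe <- fisher_2x2(tab)
message(sprintf("enrichment 2x2 [%d %d / %d %d]: OR = %.2f, p = %.3g",
                tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2],
                fe$odds_ratio, fe$p_value))
jsonlite::write_json(
  list(table = as.vector(tab), odds_ratio = fe$odds_ratio,
       p_value = fe$p_value),
  "results/validation/enrichment.json", auto_unbox = TRUE, digits = NA)
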