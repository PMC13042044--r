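#!/usr/bin/env Rscript
# Apply the sample inclusion filters and covariate binning to the
# discovery cohort metadata, and persist the kept profiles plus an
# exclusion log with one reason per dropped sample.
suppressPackageStartupMessages(library(sexbiome))

cohort <- read_cohort("results/data/discovery")
qc <- filter_samples(cohort$metadata)
message(sprintf("QC: kept %d of %d samples (%d excluded)",
                nrow(qc$kept), nrow(cohort$metadata),
                nrow(qc$exclusion_log)))
if (nrow(qc$exclusion_log) > 0)
  print(table(qc$exclusion_log$reason))

profiles <- bin_covariates(qc$kept)
dir.create("results/qc", showWarnings = FALSE, recursive = TRUE)
write.table(profiles, "results/qc/covariate_profiles.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(qc$exclusion_log, "results/qc/exclusion_log.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("covariate bins in use:")
for (col in c("age_bin", "bmi_bin", "read_length_bin", "depth_bin",
              "kit_bin"))
  message(sprintf("  %s: %s", col,
                  paste(names(table(profiles[[col]])), collapse = ", ")))
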