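#!/usr/bin/env Rscript
# Scan the proteome for windows matching the anchor epitope at the
# required positions (2, 5, 7, 8), score full-window identity, and check
# the distinct-protein count against the planted truth.
suppressPackageStartupMessages(library(sexbiome))

pattern <- motif_pattern("YRSPFSRVV", c(2, 5, 7, 8))
scan <- scan_proteome("results/data/proteome.faa", pattern,
                      top_hit_threshold = 0.5)
truth <- read_truth("results/data/proteome_truth.tsv")

dir.create("results/mimicry", showWarnings = FALSE, recursive = TRUE)
write.table(scan$hits, "results/mimicry/hits.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
jsonlite::write_json(
  list(distinct_proteins = scan$distinct_proteins,
       hit_windows = nrow(scan$hits),
       top_hits = sum(scan$hits$is_top_hit),
       planted = sum(truth$planted),
       all_planted_recovered =
         setequal(unique(scan$hits$protein_id),
                  truth$protein_id[truth$planted])),
  "results/mimicry/summary.json", auto_unbox = TRUE)
message(sprintf(
  "mimicry scan: %d hit windows in %d distinct proteins (%d planted); %d top hits",
  nrow(scan$hits), scan$distinct_proteins, sum(truth$planted),
  sum(scan$hits$is_top_hit)))
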