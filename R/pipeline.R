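#' Run the full sex-association analysis pipeline
#'
#' Orchestrates the stages end to end: obtain a cohort (simulate from a
#' synthetic specification, or load TSVs written by [write_cohort()]),
#' apply sample QC and covariate binning, CLR-transform, fit the abundance
#' (mixed) and prevalence (logistic) sex models, BH-adjust, select
#' significant and high-confidence species, and optionally validate the
#' high-confidence set in a synthetic case-control cohort and scan a
#' proteome for mimicry motifs.  Every artifact is written as plain TSV or
#' JSON and the run manifest records the seed, a config hash and per-stage
#' row counts, so identical configurations reproduce identical outputs.
#'
#' @param config a named list (or path to a YAML/JSON file) with elements:
#'   exactly one of `synthetic` (arguments for [synthetic_cohort_spec()])
#'   or `input` (directory for [read_cohort()]); optional `selection`
#'   (arguments for [selection_criteria()]), `detection_threshold`,
#'   `pseudocount`, `seed`, `out_dir`; optional `validation` (list with
#'   `n_cases`, `n_controls`, optional `disease_effects`,
#'   `severity_effects`); optional `mimicry` (list with `fasta` or
#'   `proteins`, `anchor`, `positions`, optional `top_hit_threshold`).
#' @return The manifest, invisibly; artifacts under `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  config <- .load_config(config)
  .validate_config(config)
  out_dir <- config$out_dir %||% tempfile("sexbiome_run_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  manifest <- list(package = "sexbiome",
                   version = as.character(utils::packageVersion("sexbiome")),
                   seed = seed,
                   config_hash = .config_hash(config),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   stages = list(), files = list())
  log_stage <- function(name, ...) {
    t0 <- Sys.time()
    counts <- list(...)
    message(sprintf("[%s] %s", name,
                    paste(names(counts), unlist(counts), sep = "=",
                          collapse = ", ")))
    manifest$stages[[name]] <<- counts
    invisible(NULL)
  }

  # --- stage: simulate or load -------------------------------------------
  truth <- NULL
  if (!is.null(config$synthetic)) {
    syn <- config$synthetic[setdiff(names(config$synthetic), "seed")]
    spec <- do.call(synthetic_cohort_spec, c(syn, list(seed = seed)))
    gen <- generate_meta_cohorts(spec)
    cohort <- gen$cohort
    truth <- gen$truth
    write_truth(truth, file.path(out_dir, "truth.tsv"))
    manifest$files$truth <- "truth.tsv"
  } else {
    cohort <- read_cohort(config$input)
  }
  log_stage("cohort", species = nrow(cohort$abundance),
            samples = ncol(cohort$abundance))

  # --- stage: QC ---------------------------------------------------------
  qc <- filter_samples(cohort$metadata)
  utils::write.table(qc$exclusion_log,
                     file.path(out_dir, "exclusion_log.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest$files$exclusion_log <- "exclusion_log.tsv"
  keep_ids <- qc$kept$sample_id
  abundance <- cohort$abundance[, keep_ids, drop = FALSE]
  # renormalise in case QC dropped samples (columns are independent)
  profiles <- bin_covariates(qc$kept)
  log_stage("qc", kept = length(keep_ids),
            excluded = nrow(qc$exclusion_log))

  # --- stage: associate --------------------------------------------------
  detection_threshold <- config$detection_threshold %||% 0
  pseudocount <- config$pseudocount %||% "half_min_nonzero"
  clr <- clr_transform(abundance, pseudocount)
  detected <- abundance > detection_threshold
  rec_ab <- fit_abundance_model(clr, profiles, detected = detected)
  rec_pr <- fit_prevalence_model(abundance, profiles,
                                 detection_threshold = detection_threshold)
  records <- adjust_fdr(rbind(rec_ab, rec_pr))
  for (m in c("abundance", "prevalence")) {
    f <- sprintf("associations_%s.tsv", m)
    utils::write.table(records[records$model == m, ],
                       file.path(out_dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    manifest$files[[paste0("associations_", m)]] <- f
  }
  log_stage("associate",
            tested_abundance = sum(rec_ab$fit_status == "ok"),
            tested_prevalence = sum(rec_pr$fit_status == "ok"))

  # --- stage: select -----------------------------------------------------
  criteria <- do.call(selection_criteria, config$selection %||% list())
  sig <- select_significant(records, criteria)
  hc <- select_high_confidence(records, criteria)
  counts <- intersect_models(hc)
  utils::write.table(hc, file.path(out_dir, "high_confidence.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest$files$high_confidence <- "high_confidence.tsv"
  summary <- list(
    significant_abundance = sum(sig$model == "abundance"),
    significant_prevalence = sum(sig$model == "prevalence"),
    significant_union = length(unique(sig$species_id)),
    high_confidence_union = nrow(hc),
    high_confidence_female = sum(hc$direction == "female"),
    high_confidence_male = sum(hc$direction == "male"),
    consistent_both = hc$species_id[hc$consistent_both],
    intersection_counts = counts)
  jsonlite::write_json(summary, file.path(out_dir, "selection_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest$files$selection_summary <- "selection_summary.json"
  log_stage("select", significant = length(unique(sig$species_id)),
            high_confidence = nrow(hc))

  # --- stage: validate (optional) ----------------------------------------
  if (!is.null(config$validation)) {
    v <- config$validation
    vc <- generate_validation_cohort(
      n_cases = v$n_cases, n_controls = v$n_controls,
      disease_effects = unlist(v$disease_effects) %||% numeric(),
      severity_effects = unlist(v$severity_effects) %||% numeric(),
      seed = sub_seed(seed, 11L),
      n_species = v$n_species %||% 100L)
    cand <- if (nrow(hc) > 0) hc$species_id else rownames(vc$abundance)
    val <- rbind(fit_disease_model(vc, cand),
                 fit_severity_model(vc, cand))
    utils::write.table(val, file.path(out_dir, "validation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$files$validation <- "validation.tsv"
    log_stage("validate", candidates = length(cand),
              tested = sum(val$status == "tested"))
  }

  # --- stage: scan (optional) --------------------------------------------
  if (!is.null(config$mimicry)) {
    m <- config$mimicry
    pat <- motif_pattern(m$anchor, unlist(m$positions))
    scan <- scan_proteome(m$fasta %||% m$proteins, pat,
                          top_hit_threshold = m$top_hit_threshold %||% 0.5)
    utils::write.table(scan$hits, file.path(out_dir, "mimicry_hits.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$files$mimicry_hits <- "mimicry_hits.tsv"
    log_stage("scan", hits = nrow(scan$hits),
              distinct_proteins = scan$distinct_proteins)
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

.load_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stopf("reading YAML configs requires the yaml package")
      return(yaml::read_yaml(config))
    }
    return(jsonlite::read_json(config, simplifyVector = TRUE))
  }
  if (!is.list(config)) stopf("config must be a list or a file path")
  config
}

.validate_config <- function(config) {
  has_in <- !is.null(config$input)
  has_syn <- !is.null(config$synthetic)
  if (has_in == has_syn)
    stopf("config must contain exactly one of 'input' or 'synthetic'")
  invisible(TRUE)
}

# Stable hash of the analytic configuration (output location excluded):
# md5 of its canonical JSON serialisation.
.config_hash <- function(config) {
  config <- config[setdiff(names(config), "out_dir")]
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  ser <- jsonlite::serializeJSON(config[order(names(config))])
  writeLines(ser, f)
  unname(tools::md5sum(f))
}
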