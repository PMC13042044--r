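#' Specification for a synthetic multi-study cohort
#'
#' Defines the generative conditions for [generate_meta_cohorts()]: a
#' multi-study collection of compositional species profiles with study-level
#' random intercepts, sparse detection, planted sex effects on a known
#' species subset, and independent covariates.  Defaults emulate a
#' moderately deep shotgun survey of prevalent gut species: eight studies of
#' one hundred stool samples, two hundred species of which twenty carry a
#' one log-unit sex effect, study heterogeneity at half the residual spread,
#' and ninety-five percent baseline detection moderately tied to latent
#' abundance, so planted abundance effects carry a matching (weaker)
#' prevalence signal while one latent log-unit stays close to one CLR unit
#' in analysis space.
#'
#' @param n_studies number of studies.
#' @param samples_per_study samples per study (one sample per individual).
#' @param n_species number of species.
#' @param n_sex_assoc number of species carrying a planted sex effect.
#' @param sex_effect_size absolute latent log-abundance shift added for one
#'   sex on planted species; signs alternate so both female- and
#'   male-enriched species exist.
#' @param study_sd standard deviation of the per-study, per-species random
#'   intercept (log-abundance units).
#' @param residual_sd residual standard deviation (log-abundance units).
#' @param covariate_effects named numeric vector mapping covariate name
#'   (`age`, `bmi`, `health`) to an effect scale; each covariate acts on the
#'   latent scale through species-specific loadings.
#' @param detection_slope logit-scale slope linking latent log abundance to
#'   the detection probability.
#' @param base_detection detection probability for a species at latent 0.
#' @param seed integer seed; fully determines the output.
#' @return An object of class `synthetic_cohort_spec`.
#' @export
synthetic_cohort_spec <- function(n_studies = 8L,
                                  samples_per_study = 100L,
                                  n_species = 200L,
                                  n_sex_assoc = 20L,
                                  sex_effect_size = 1.0,
                                  study_sd = 0.5,
                                  residual_sd = 1.0,
                                  covariate_effects = c(age = 0.3,
                                                        bmi = 0.2,
                                                        health = 0.3),
                                  detection_slope = 0.5,
                                  base_detection = 0.95,
                                  seed = 1L) {
  counts <- c(n_studies = n_studies, samples_per_study = samples_per_study,
              n_species = n_species)
  if (any(counts <= 0)) stopf("all counts must be > 0")
  if (n_sex_assoc < 0) stopf("n_sex_assoc must be >= 0")
  if (n_sex_assoc > n_species)
    stopf("invalid spec: n_sex_assoc (%d) exceeds n_species (%d)",
          n_sex_assoc, n_species)
  if (study_sd < 0 || residual_sd < 0) stopf("SDs must be >= 0")
  if (base_detection <= 0 || base_detection >= 1)
    stopf("base_detection must lie in (0, 1)")
  structure(list(n_studies = as.integer(n_studies),
                 samples_per_study = as.integer(samples_per_study),
                 n_species = as.integer(n_species),
                 n_sex_assoc = as.integer(n_sex_assoc),
                 sex_effect_size = sex_effect_size,
                 study_sd = study_sd, residual_sd = residual_sd,
                 covariate_effects = covariate_effects,
                 detection_slope = detection_slope,
                 base_detection = base_detection,
                 seed = as.integer(seed)),
            class = "synthetic_cohort_spec")
}

# Sample-level metadata, every field the QC stage requires.  All samples are
# generated QC-clean; QC failures are exercised with hand-built tables.
.sample_metadata <- function(n, study_ids) {
  data.frame(
    sample_id = make_ids("S", n),
    study_id = study_ids,
    sex = sample(c("female", "male"), n, replace = TRUE),
    age = round(stats::runif(n, 18, 85), 1),
    bmi = round(pmin(pmax(stats::rnorm(n, 25, 4), 15), 45), 1),
    continent = sample(c("Europe", "NorthAmerica", "Asia", "Africa"),
                       n, replace = TRUE),
    health = sample(c("healthy", "diseased"), n, replace = TRUE,
                    prob = c(0.7, 0.3)),
    antibiotics_current = FALSE,
    body_site = "stool",
    mean_read_depth = stats::runif(n, 2.5e7, 1.5e8),
    median_read_length = round(stats::runif(n, 81, 160)),
    extraction_kit = sample(c("Qiagen", "unknown", "other"),
                            n, replace = TRUE),
    stringsAsFactors = FALSE)
}

# Latent log abundances -> closed composition -> Bernoulli detection zeros.
.close_and_detect <- function(latent, base_detection, detection_slope) {
  p_detect <- stats::plogis(stats::qlogis(base_detection) +
                              detection_slope * latent)
  detected <- matrix(stats::rbinom(length(p_detect), 1L, p_detect),
                     nrow = nrow(latent))
  expl <- exp(latent) * detected
  # guard: a sample where nothing was detected keeps its most abundant species
  empty <- colSums(expl) == 0
  if (any(empty)) {
    top <- apply(latent[, empty, drop = FALSE], 2, which.max)
    expl[cbind(top, which(empty))] <- exp(latent[cbind(top, which(empty))])
  }
  sweep(expl, 2, colSums(expl), "/")
}

#' Generate a synthetic multi-study cohort with planted sex effects
#'
#' Latent per-sample log abundances are built additively: a species baseline,
#' a per-study-per-species random intercept `Normal(0, study_sd)`, the
#' planted sex effect (female-positive coding) on the designated species,
#' species-loaded covariate effects, and `Normal(0, residual_sd)` noise.
#' The latent matrix is closed to relative abundances by exponentiation and
#' per-sample normalisation; each entry is then observed only if a Bernoulli
#' detection indicator with probability
#' `logistic(logit(base_detection) + detection_slope * latent)` fires, after
#' which the detected entries are renormalised.  Zeros therefore arise only
#' through detection, matching a binomial prevalence model.
#'
#' @param spec a [synthetic_cohort_spec()].
#' @return A list with elements `cohort` (a [cohort_table()]) and `truth`
#'   (data.frame: `species_id`, `true_sex_effect`, `true_direction`,
#'   `planted_in`).
#' @export
generate_meta_cohorts <- function(spec) {
  stopifnot(inherits(spec, "synthetic_cohort_spec"))
  with_seed(spec$seed, {
    n <- spec$n_studies * spec$samples_per_study
    S <- spec$n_species
    study_ids <- rep(make_ids("study", spec$n_studies),
                     each = spec$samples_per_study)
    md <- .sample_metadata(n, study_ids)
    species <- make_ids("sp", S)

    baseline <- stats::rnorm(S, 0, 1.5)
    study_fx <- matrix(stats::rnorm(S * spec$n_studies, 0, spec$study_sd),
                       nrow = S)
    colnames(study_fx) <- unique(study_ids)

    planted <- seq_len(spec$n_sex_assoc)
    effect <- numeric(S)
    if (spec$n_sex_assoc > 0 && spec$sex_effect_size != 0)
      effect[planted] <- spec$sex_effect_size *
        rep_len(c(1, -1), spec$n_sex_assoc)

    latent <- matrix(baseline, nrow = S, ncol = n) +
      study_fx[, md$study_id] +
      outer(effect, as.numeric(md$sex == "female")) +
      matrix(stats::rnorm(S * n, 0, spec$residual_sd), nrow = S)

    cov_x <- list(age = as.numeric(scale(md$age)),
                  bmi = as.numeric(scale(md$bmi)),
                  health = as.numeric(md$health == "diseased"))
    for (nm in names(spec$covariate_effects)) {
      if (!nm %in% names(cov_x))
        stopf("unknown covariate in covariate_effects: %s", nm)
      loading <- stats::rnorm(S)
      latent <- latent +
        spec$covariate_effects[[nm]] * outer(loading, cov_x[[nm]])
    }

    rel <- .close_and_detect(latent, spec$base_detection,
                             spec$detection_slope)
    dimnames(rel) <- list(species, md$sample_id)

    direction <- ifelse(effect > 0, "female",
                        ifelse(effect < 0, "male", "none"))
    planted_in <- ifelse(effect == 0, "none",
                         ifelse(spec$detection_slope != 0, "both",
                                "abundance"))
    truth <- data.frame(species_id = species, true_sex_effect = effect,
                        true_direction = direction, planted_in = planted_in,
                        stringsAsFactors = FALSE)
    list(cohort = cohort_table(rel, md), truth = truth)
  })
}

#' Generate a synthetic case-control validation cohort
#'
#' Emulates a paired case-control microbiome cohort: metadata carries
#' disease status, a clinical severity score (EDSS, 0 for controls), sex and
#' treatment status.  Planted species shift their latent log abundance by
#' `disease_effects` in cases and by `severity_effects` per EDSS unit.
#'
#' @param n_cases,n_controls sample counts, both `> 0`.
#' @param disease_effects named numeric vector, species id to latent
#'   log-abundance shift in cases.
#' @param severity_effects named numeric vector, species id to latent slope
#'   per EDSS unit.
#' @param seed integer seed.
#' @param n_species number of species in the cohort.
#' @param base_detection,detection_slope detection model as in
#'   [synthetic_cohort_spec()]; defaults give the denser detection typical
#'   of a single deeply sequenced cohort.
#' @param residual_sd residual latent standard deviation.
#' @return A [cohort_table()] whose metadata has columns `sample_id`,
#'   `disease`, `edss`, `sex`, `treatment`.
#' @export
generate_validation_cohort <- function(n_cases, n_controls,
                                       disease_effects = numeric(),
                                       severity_effects = numeric(),
                                       seed = 1L,
                                       n_species = 100L,
                                       base_detection = 0.98,
                                       detection_slope = 0.25,
                                       residual_sd = 1.0) {
  if (n_cases <= 0 || n_controls <= 0)
    stopf("n_cases and n_controls must be > 0")
  species <- make_ids("sp", n_species)
  for (nm in c(names(disease_effects), names(severity_effects)))
    if (!nm %in% species)
      stopf("effect map references unknown species: %s", nm)
  with_seed(seed, {
    n <- n_cases + n_controls
    md <- data.frame(
      sample_id = make_ids("V", n),
      disease = rep(c("MS", "control"), c(n_cases, n_controls)),
      edss = c(round(stats::runif(n_cases, 0, 7) * 2) / 2,
               rep(0, n_controls)),
      sex = sample(c("female", "male"), n, replace = TRUE),
      treatment = c(sample(c("treated", "untreated"), n_cases,
                           replace = TRUE),
                    rep("untreated", n_controls)),
      stringsAsFactors = FALSE)

    baseline <- stats::rnorm(n_species, 0, 1.5)
    latent <- matrix(baseline, nrow = n_species, ncol = n) +
      matrix(stats::rnorm(n_species * n, 0, residual_sd), nrow = n_species)
    is_case <- as.numeric(md$disease == "MS")
    for (nm in names(disease_effects))
      latent[match(nm, species), ] <-
        latent[match(nm, species), ] + disease_effects[[nm]] * is_case
    for (nm in names(severity_effects))
      latent[match(nm, species), ] <-
        latent[match(nm, species), ] + severity_effects[[nm]] * md$edss

    rel <- .close_and_detect(latent, base_detection, detection_slope)
    dimnames(rel) <- list(species, md$sample_id)
    cohort_table(rel, md)
  })
}

#' Generate a synthetic proteome with planted positional motifs
#'
#' Writes random amino-acid sequences in which exactly `n_planted` proteins
#' contain at least one window matching `anchor` at the `positions` residues
#' (planted by construction); every other protein is rejection-sampled to
#' contain no matching window, so a scanner should report exactly
#' `n_planted` distinct proteins.
#'
#' @param n_proteins number of proteins.
#' @param length_range integer vector of length 2, inclusive protein length
#'   bounds.
#' @param anchor anchor peptide (uppercase one-letter residues).
#' @param positions 1-based required positions within the anchor.
#' @param n_planted number of proteins to plant a motif into.
#' @param seed integer seed.
#' @param fasta optional path; when given, records are written there as
#'   FASTA.
#' @return A list with `proteins` (named character vector of sequences),
#'   `truth` (data.frame: `protein_id`, `planted`, `offset`) and `fasta`
#'   (path or `NA`).
#' @export
generate_proteome <- function(n_proteins, length_range, anchor, positions,
                              n_planted, seed = 1L, fasta = NULL) {
  pattern <- motif_pattern(anchor, positions)
  L <- nchar(anchor)
  if (n_planted > n_proteins)
    stopf("n_planted (%d) exceeds n_proteins (%d)", n_planted, n_proteins)
  if (L > min(length_range))
    stopf("anchor length %d exceeds minimum protein length %d",
          L, min(length_range))
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  with_seed(seed, {
    lens <- sample(seq(length_range[1], length_range[2]), n_proteins,
                   replace = TRUE)
    ids <- make_ids("prot", n_proteins)
    planted_idx <- if (n_planted > 0) sort(sample(n_proteins, n_planted))
                   else integer()
    seqs <- character(n_proteins)
    offsets <- rep(NA_integer_, n_proteins)
    for (i in seq_len(n_proteins)) {
      repeat {
        chars <- sample(aa, lens[i], replace = TRUE)
        if (length(.match_offsets(chars, pattern)) == 0) break
      }
      if (i %in% planted_idx) {
        off <- sample(lens[i] - L + 1L, 1L)
        window <- sample(aa, L, replace = TRUE)
        window[pattern$required_positions] <-
          strsplit(pattern$anchor, "")[[1]][pattern$required_positions]
        chars[off:(off + L - 1L)] <- window
        offsets[i] <- off
      }
      seqs[i] <- paste(chars, collapse = "")
    }
    names(seqs) <- ids
    truth <- data.frame(protein_id = ids,
                        planted = seq_len(n_proteins) %in% planted_idx,
                        offset = offsets, stringsAsFactors = FALSE)
    path <- NA_character_
    if (!is.null(fasta)) {
      Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), fasta)
      path <- fasta
    }
    list(proteins = seqs, truth = truth, fasta = path)
  })
}

#' Write and read a ground-truth table
#'
#' Plain-TSV round trip for the truth tables emitted beside every generated
#' dataset.
#'
#' @param truth truth data.frame.
#' @param path TSV path.
#' @return `write_truth` returns the path invisibly; `read_truth` the
#'   data.frame.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
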