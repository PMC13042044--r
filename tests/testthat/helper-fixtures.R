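# Shared fixtures, all generated in code.

# Toy metadata: six samples each violating one distinct inclusion
# criterion, plus one clean sample.
toy_qc_metadata <- function() {
  base <- data.frame(
    sample_id = sprintf("t%02d", 1:7),
    study_id = "studyA",
    sex = "female", age = 35, bmi = 24, continent = "Europe",
    health = "healthy", antibiotics_current = FALSE, body_site = "stool",
    mean_read_depth = 5e7, median_read_length = 120,
    extraction_kit = "Qiagen", stringsAsFactors = FALSE)
  base$antibiotics_current[1] <- TRUE
  base$antibiotics_current[2] <- NA
  base$mean_read_depth[3] <- 2e7          # boundary: <= 20M excluded
  base$median_read_length[4] <- 80        # boundary: <= 80 excluded
  base$body_site[5] <- "skin"
  base$bmi[6] <- NA                       # model covariate missing
  base
}

# A small multi-study cohort fitted once and cached: used by invariance
# and selection tests that need realistic association records.
fitted_small_cohort <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    spec <- synthetic_cohort_spec(n_studies = 4, samples_per_study = 50,
                                  n_species = 40, n_sex_assoc = 4,
                                  sex_effect_size = 1.5, seed = 42)
    gen <- generate_meta_cohorts(spec)
    qc <- filter_samples(gen$cohort$metadata)
    prof <- bin_covariates(qc$kept)
    ab <- gen$cohort$abundance[, qc$kept$sample_id, drop = FALSE]
    clr <- clr_transform(ab)
    rec <- adjust_fdr(rbind(
      fit_abundance_model(clr, prof, detected = ab > 0),
      fit_prevalence_model(ab, prof)))
    cache <<- list(gen = gen, prof = prof, ab = ab, clr = clr,
                   records = rec)
    cache
  }
})

# Hand-built association records for selection-rule tests.
make_records <- function(model, beta, q, direction = NULL) {
  n <- length(beta)
  data.frame(species_id = sprintf("sp%03d", seq_len(n)),
             model = model, beta_sex = beta, se = 0.1,
             p_value = q, q_value = q,
             direction = direction %||% ifelse(beta > 0, "female", "male"),
             n_used = 100L, fit_status = "ok", stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent BH oracle: q_i = min over the p-sorted tail of p * m / rank.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# Independent two-sided Fisher p oracle by hypergeometric enumeration.
fisher_oracle <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  m1 <- a + b; m2 <- c_ + d; n1 <- a + c_
  lo <- max(0, n1 - m2); hi <- min(n1, m1)
  probs <- dhyper(lo:hi, m1, m2, n1)
  p_obs <- dhyper(a, m1, m2, n1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
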