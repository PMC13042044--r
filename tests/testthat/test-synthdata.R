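test_that("the same seed reproduces a byte-identical cohort", {
  spec <- synthetic_cohort_spec(n_studies = 2, samples_per_study = 20,
                                n_species = 15, n_sex_assoc = 3, seed = 7)
  g1 <- generate_meta_cohorts(spec)
  g2 <- generate_meta_cohorts(spec)
  expect_identical(g1, g2)
  d1 <- tempfile(); d2 <- tempfile()
  write_cohort(g1$cohort, d1); write_cohort(g2$cohort, d2)
  expect_identical(unname(tools::md5sum(file.path(d1, "abundance.tsv"))),
                   unname(tools::md5sum(file.path(d2, "abundance.tsv"))))
  expect_identical(unname(tools::md5sum(file.path(d1, "metadata.tsv"))),
                   unname(tools::md5sum(file.path(d2, "metadata.tsv"))))
})

test_that("a zero effect size yields an all-null truth table", {
  spec <- synthetic_cohort_spec(n_studies = 2, samples_per_study = 10,
                                n_species = 12, n_sex_assoc = 4,
                                sex_effect_size = 0, seed = 3)
  gen <- generate_meta_cohorts(spec)
  expect_true(all(gen$truth$true_direction == "none"))
  expect_true(all(gen$truth$true_sex_effect == 0))
  expect_true(all(gen$truth$planted_in == "none"))
})

test_that("truth direction is consistent with the effect sign and species appear once", {
  spec <- synthetic_cohort_spec(n_studies = 2, samples_per_study = 10,
                                n_species = 30, n_sex_assoc = 10, seed = 5)
  tr <- generate_meta_cohorts(spec)$truth
  expect_equal(anyDuplicated(tr$species_id), 0)
  expect_equal(nrow(tr), 30)
  expect_true(all(tr$true_direction[tr$true_sex_effect > 0] == "female"))
  expect_true(all(tr$true_direction[tr$true_sex_effect < 0] == "male"))
})

test_that("invalid specifications are rejected", {
  expect_error(synthetic_cohort_spec(n_sex_assoc = 10, n_species = 5),
               "invalid spec")
  expect_error(synthetic_cohort_spec(n_studies = 0), "counts")
  expect_error(synthetic_cohort_spec(study_sd = -1), "SDs")
  expect_error(generate_validation_cohort(0, 10), "> 0")
  expect_error(generate_validation_cohort(10, 10,
                                          disease_effects = c(nope = 1)),
               "unknown species")
})

test_that("sample compositions sum to one after zero-renormalisation", {
  for (s in 1:3) {
    spec <- synthetic_cohort_spec(n_studies = 2, samples_per_study = 25,
                                  n_species = 40, n_sex_assoc = 5,
                                  base_detection = 0.7, seed = s)
    ab <- generate_meta_cohorts(spec)$cohort$abundance
    expect_lt(max(abs(colSums(ab) - 1)), 1e-9)
    expect_true(all(ab >= 0))
  }
})

test_that("generated metadata carries every QC covariate and passes QC", {
  gen <- generate_meta_cohorts(synthetic_cohort_spec(
    n_studies = 2, samples_per_study = 15, n_species = 10,
    n_sex_assoc = 2, seed = 2))
  qc <- filter_samples(gen$cohort$metadata)
  expect_equal(nrow(qc$kept), 30)
  expect_equal(nrow(qc$exclusion_log), 0)
  expect_no_error(bin_covariates(qc$kept))
})

test_that("truth tables round-trip through TSV unchanged", {
  tr <- generate_meta_cohorts(synthetic_cohort_spec(
    n_studies = 2, samples_per_study = 5, n_species = 8,
    n_sex_assoc = 2, seed = 9))$truth
  f <- tempfile(fileext = ".tsv")
  write_truth(tr, f)
  expect_equal(read_truth(f), tr)
})

test_that("cohort tables round-trip through their TSV pair", {
  gen <- generate_meta_cohorts(synthetic_cohort_spec(
    n_studies = 2, samples_per_study = 6, n_species = 7,
    n_sex_assoc = 1, seed = 4))
  d <- tempfile()
  write_cohort(gen$cohort, d)
  back <- read_cohort(d)
  expect_equal(back$abundance, gen$cohort$abundance, tolerance = 1e-12)
  expect_equal(back$metadata$sample_id, gen$cohort$metadata$sample_id)
})

test_that("null generator yields uniform abundance-model p-values", {
  # 200 species x 5 seeds; Kolmogorov-Smirnov on the pooled p-values
  ps <- unlist(lapply(1:5, function(s) {
    spec <- synthetic_cohort_spec(sex_effect_size = 0, seed = 100 + s)
    gen <- generate_meta_cohorts(spec)
    qc <- filter_samples(gen$cohort$metadata)
    prof <- bin_covariates(qc$kept)
    ab <- gen$cohort$abundance[, qc$kept$sample_id, drop = FALSE]
    rec <- fit_abundance_model(clr_transform(ab), prof, detected = ab > 0)
    rec$p_value[rec$fit_status == "ok"]
  }))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("a null validation cohort rarely produces FDR discoveries", {
  # all effects zero: no species at FDR < 0.05 in >= 95% of 20 runs
  clean <- vapply(1:20, function(s) {
    vc <- generate_validation_cohort(100, 100, seed = 200 + s,
                                     n_species = 50)
    dm <- fit_disease_model(vc, rownames(vc$abundance))
    sum(dm$q_value < 0.05, na.rm = TRUE) == 0
  }, logical(1))
  expect_gte(mean(clean), 0.95)
})

test_that("a planted disease effect dominates the validation ranking", {
  # effect +1.0 on one species, n = 200/200: first by p in >= 9/10 seeds
  stats_ <- vapply(1:10, function(s) {
    vc <- generate_validation_cohort(200, 200,
                                     disease_effects = c(sp010 = 1.0),
                                     seed = s)
    dm <- fit_disease_model(vc, rownames(vc$abundance))
    c(first = dm$species_id[which.min(dm$p_value)] == "sp010",
      strong = dm$beta_term[dm$species_id == "sp010"] > 0 &&
        dm$p_value[dm$species_id == "sp010"] < 1e-3)
  }, logical(2))
  expect_gte(sum(stats_["first", ]), 9)
  expect_gte(sum(stats_["strong", ]), 9)
})

test_that("proteome generation is seed-deterministic and plants exactly", {
  pat_anchor <- "YRSPFSRVV"
  g1 <- generate_proteome(50, c(60, 200), pat_anchor, c(2, 5, 7, 8),
                          n_planted = 5, seed = 11)
  g2 <- generate_proteome(50, c(60, 200), pat_anchor, c(2, 5, 7, 8),
                          n_planted = 5, seed = 11)
  expect_identical(g1$proteins, g2$proteins)
  expect_equal(sum(g1$truth$planted), 5)

  scan <- scan_proteome(g1$proteins,
                        motif_pattern(pat_anchor, c(2, 5, 7, 8)))
  expect_equal(scan$distinct_proteins, 5)
  expect_setequal(unique(scan$hits$protein_id),
                  g1$truth$protein_id[g1$truth$planted])

  g0 <- generate_proteome(30, c(60, 200), pat_anchor, c(2, 5, 7, 8),
                          n_planted = 0, seed = 12)
  scan0 <- scan_proteome(g0$proteins,
                         motif_pattern(pat_anchor, c(2, 5, 7, 8)))
  expect_equal(scan0$distinct_proteins, 0)

  expect_error(generate_proteome(10, c(5, 20), pat_anchor, c(2, 5),
                                 n_planted = 1, seed = 1),
               "anchor length")
  expect_error(generate_proteome(3, c(60, 80), pat_anchor, c(2, 5),
                                 n_planted = 4, seed = 1),
               "exceeds n_proteins")
})
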