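test_that("CLR of simple compositions matches closed forms", {
  u <- matrix(rep(1 / 4, 4), ncol = 1,
              dimnames = list(paste0("s", 1:4), "A"))
  expect_equal(clr_transform(u, pseudocount = "none"),
               matrix(0, 4, 1, dimnames = dimnames(u)))
  x <- matrix(c(1, 2, 4) / 7, ncol = 1,
              dimnames = list(paste0("s", 1:3), "A"))
  expect_equal(as.numeric(clr_transform(x, pseudocount = "none")),
               c(-log(2), 0, log(2)))
})

test_that("CLR agrees with an independent log/centre oracle", {
  set.seed(31)
  m <- matrix(runif(50 * 30, 0.01, 1), 50, 30,
              dimnames = list(paste0("sp", 1:50), paste0("s", 1:30)))
  m <- sweep(m, 2, colSums(m), "/")
  got <- clr_transform(m, pseudocount = "none")
  oracle <- apply(log(m), 2, function(col) col - mean(col))
  expect_equal(got, oracle, tolerance = 1e-12)
  expect_lt(max(abs(colSums(got))), 1e-9)
})

test_that("CLR columns sum to zero under the pseudocount policy too", {
  set.seed(77)
  m <- matrix(rbinom(40 * 20, 1, 0.8) * runif(40 * 20), 40, 20,
              dimnames = list(paste0("sp", 1:40), paste0("s", 1:20)))
  m <- sweep(m, 2, pmax(colSums(m), 1e-12), "/")
  expect_lt(max(abs(colSums(clr_transform(m)))), 1e-9)
})

test_that("CLR rejects all-zero samples by name and negative entries", {
  m <- matrix(c(0.5, 0.5, 0, 0), 2, 2,
              dimnames = list(c("a", "b"), c("good", "empty")))
  expect_error(clr_transform(m), "empty")
  m2 <- matrix(c(-0.1, 1.1), 2, 1,
               dimnames = list(c("a", "b"), "s"))
  expect_error(clr_transform(m2), "non-negative")
})

test_that("prevalence model reproduces the 2x2 closed-form log-odds", {
  # detection depends only on sex: 30/50 females vs 15/50 males detected
  n <- 100
  sex <- rep(c("female", "male"), each = 50)
  det <- c(rep(c(1, 0), c(30, 20)), rep(c(1, 0), c(15, 35)))
  # spread detection across two studies so the prevalence floor passes
  study <- rep(c("st1", "st2"), times = 50)
  ab <- rbind(target = det * 0.2,
              fill1 = 0.4, fill2 = 0.4)
  ab <- sweep(ab, 2, colSums(ab), "/")
  colnames(ab) <- sprintf("s%03d", 1:n)
  md <- data.frame(sample_id = colnames(ab), study_id = study, sex = sex,
                   stringsAsFactors = FALSE)
  rec <- fit_prevalence_model(ab, md)
  beta <- rec$beta_sex[rec$species_id == "target"]
  expect_equal(beta, log((30 / 20) / (15 / 35)), tolerance = 1e-6)
  expect_equal(rec$direction[rec$species_id == "target"], "female")
})

test_that("prevalence model recovers a planted sex log-odds of one", {
  beta <- vapply(1:10, function(s) {
    set.seed(s)
    n <- 800
    sex <- rep(c("female", "male"), each = n / 2)
    study <- rep(c("st1", "st2"), times = n / 2)
    det <- rbinom(n, 1, plogis(-0.5 + 1.0 * (sex == "female")))
    ab <- rbind(target = det * runif(n, 0.1, 0.3),
                fill1 = runif(n, 0.2, 0.5), fill2 = runif(n, 0.2, 0.5))
    ab <- sweep(ab, 2, colSums(ab), "/")
    colnames(ab) <- sprintf("s%03d", 1:n)
    md <- data.frame(sample_id = colnames(ab), study_id = study,
                     sex = sex, stringsAsFactors = FALSE)
    rec <- fit_prevalence_model(ab, md)
    rec$beta_sex[rec$species_id == "target"]
  }, numeric(1))
  expect_gte(sum(beta >= 0.6 & beta <= 1.4), 9)
})

test_that("degenerate prevalence outcomes are skipped, not fit", {
  fx <- fitted_small_cohort()
  ab <- fx$ab
  ab["sp001", ] <- pmax(ab["sp001", ], 1e-4)     # present everywhere
  ab["sp002", ] <- 0
  ab["sp002", 1:3] <- 0.01                       # below the 10% floor
  ab <- sweep(ab, 2, colSums(ab), "/")
  rec <- fit_prevalence_model(ab, fx$prof)
  expect_equal(rec$fit_status[rec$species_id == "sp001"],
               "skipped_low_prevalence")
  expect_equal(rec$fit_status[rec$species_id == "sp002"],
               "skipped_low_prevalence")
  expect_true(all(is.na(rec$p_value[rec$fit_status != "ok"])))
})

test_that("abundance model flags species below the prevalence floor", {
  fx <- fitted_small_cohort()
  detected <- fx$ab > 0
  detected["sp003", ] <- FALSE
  detected["sp003", 1:5] <- TRUE
  rec <- fit_abundance_model(fx$clr, fx$prof, detected = detected)
  expect_equal(rec$fit_status[rec$species_id == "sp003"],
               "skipped_low_prevalence")
})

test_that("abundance model recovers a planted one-log-unit sex effect", {
  # detection decoupled from the latent so the planted latent effect is
  # exactly the CLR estimand; 8 studies x 100 samples, effect +1.0
  beta <- vapply(1:10, function(s) {
    spec <- synthetic_cohort_spec(n_species = 100, n_sex_assoc = 1,
                                  sex_effect_size = 1.0,
                                  detection_slope = 0, seed = s)
    gen <- generate_meta_cohorts(spec)
    qc <- filter_samples(gen$cohort$metadata)
    prof <- bin_covariates(qc$kept)
    ab <- gen$cohort$abundance[, qc$kept$sample_id, drop = FALSE]
    rec <- fit_abundance_model(clr_transform(ab), prof, detected = ab > 0)
    rec$beta_sex[rec$species_id == "sp001"]
  }, numeric(1))
  expect_gte(sum(beta >= 0.7 & beta <= 1.3), 9)
})

test_that("single-study input is refused with a fixed-effects escape hatch", {
  fx <- fitted_small_cohort()
  prof1 <- fx$prof[fx$prof$study_id == fx$prof$study_id[1], , drop = FALSE]
  clr1 <- fx$clr[1:5, prof1$sample_id, drop = FALSE]
  expect_error(fit_abundance_model(clr1, prof1), "single_study")
  rec <- fit_abundance_model(clr1, prof1, single_study = "fixed")
  expect_true(any(rec$fit_status == "ok"))
})

test_that("relabelling sex negates effects and preserves p and q values", {
  fx <- fitted_small_cohort()
  prof2 <- fx$prof
  prof2$sex <- ifelse(fx$prof$sex == "male", "female", "male")
  ra2 <- fit_abundance_model(fx$clr, prof2, detected = fx$ab > 0)
  rp2 <- fit_prevalence_model(fx$ab, prof2)
  rec2 <- adjust_fdr(rbind(ra2, rp2))
  ok <- fx$records$fit_status == "ok" & rec2$fit_status == "ok"
  # REML optimiser tolerance bounds the mixed-model agreement near 1e-8
  expect_lt(max(abs(fx$records$beta_sex + rec2$beta_sex)[ok]), 1e-7)
  expect_lt(max(abs(fx$records$p_value - rec2$p_value)[ok]), 1e-7)
  expect_lt(max(abs(fx$records$q_value - rec2$q_value)[ok]), 1e-7)
})

test_that("direction labels follow the female-positive coding", {
  fx <- fitted_small_cohort()
  ok <- fx$records$fit_status == "ok"
  expect_true(all((fx$records$beta_sex[ok] > 0) ==
                    (fx$records$direction[ok] == "female")))
})

test_that("BH adjustment matches hand-applied step-up cases", {
  r1 <- make_records("abundance", beta = 1, q = 0.03)
  r1$q_value <- NA
  r1$p_value <- 0.03
  expect_equal(adjust_fdr(r1)$q_value, 0.03)

  r4 <- make_records("abundance", beta = rep(1, 4), q = NA)
  r4$p_value <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(adjust_fdr(r4)$q_value, rep(0.04, 4))

  expect_equal(nrow(adjust_fdr(r4[0, ])), 0)
})

test_that("q values dominate p values and adjustment is per model family", {
  set.seed(8)
  ra <- make_records("abundance", beta = rnorm(20), q = NA)
  ra$p_value <- runif(20)
  rp <- make_records("prevalence", beta = rnorm(20), q = NA)
  rp$p_value <- runif(20)
  out <- adjust_fdr(rbind(ra, rp))
  expect_true(all(out$q_value >= out$p_value))
  expect_equal(out$q_value[out$model == "abundance"],
               bh_oracle(ra$p_value))
  expect_equal(out$q_value[out$model == "prevalence"],
               bh_oracle(rp$p_value))
})

test_that("null cohorts produce a calibrated type-I error rate", {
  frac <- vapply(1:5, function(s) {
    spec <- synthetic_cohort_spec(n_studies = 4, samples_per_study = 60,
                                  n_species = 60, sex_effect_size = 0,
                                  seed = 300 + s)
    gen <- generate_meta_cohorts(spec)
    qc <- filter_samples(gen$cohort$metadata)
    prof <- bin_covariates(qc$kept)
    ab <- gen$cohort$abundance[, qc$kept$sample_id, drop = FALSE]
    rec <- fit_abundance_model(clr_transform(ab), prof, detected = ab > 0)
    mean(rec$p_value[rec$fit_status == "ok"] < 0.05)
  }, numeric(1))
  expect_lt(abs(mean(frac) - 0.05), 0.03)
})
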