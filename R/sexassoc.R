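#' Centred log-ratio transform of a relative-abundance matrix
#'
#' Per sample (column), `clr_i = ln(x_i + eps) - mean_j ln(x_j + eps)`.
#' The pseudocount `eps` handles zeros: the default policy uses half the
#' smallest non-zero relative abundance in the whole table, applied
#' uniformly; `"none"` uses `eps = 0` (only valid for strictly positive
#' data); a number is used as given.
#'
#' @param abundance numeric matrix, species x samples, non-negative; every
#'   column must have at least one positive entry.
#' @param pseudocount `"half_min_nonzero"` (default), `"none"`, or a
#'   non-negative number.
#' @return Matrix of CLR values with the input's dimnames; every column
#'   sums to 0 (within numerical tolerance).
#' @export
clr_transform <- function(abundance, pseudocount = "half_min_nonzero") {
  if (any(abundance < 0)) stopf("abundance entries must be non-negative")
  zero_cols <- colSums(abundance) == 0
  if (any(zero_cols))
    stopf("all-zero sample column(s): %s",
          paste(utils::head(colnames(abundance)[zero_cols] %||%
                              which(zero_cols), 5), collapse = ", "))
  eps <- if (is.numeric(pseudocount)) {
    if (pseudocount < 0) stopf("pseudocount must be >= 0")
    pseudocount
  } else if (identical(pseudocount, "half_min_nonzero")) {
    min(abundance[abundance > 0]) / 2
  } else if (identical(pseudocount, "none")) {
    0
  } else stopf("unknown pseudocount policy: %s", pseudocount)
  lg <- log(abundance + eps)
  sweep(lg, 2, colMeans(lg), "-")
}

# Fixed-effect terms observed with >= 2 levels; sex must vary.
.fixed_terms <- function(metadata) {
  candidates <- c("sex", "age_bin", "bmi_bin", "continent", "health",
                  "read_length_bin", "depth_bin", "kit_bin")
  present <- intersect(candidates, names(metadata))
  varying <- present[vapply(metadata[present],
                            function(x) length(unique(x)) >= 2, logical(1))]
  if (!"sex" %in% varying)
    stopf("sex does not vary in the metadata; no sex model can be fit")
  varying
}

.model_frame <- function(metadata) {
  mf <- metadata
  mf$sex <- factor(mf$sex, levels = c("male", "female"))
  if (anyNA(mf$sex)) stopf("sex must be 'male' or 'female'")
  mf
}

.assoc_record <- function(species, model, n_used) {
  data.frame(species_id = species, model = model,
             beta_sex = NA_real_, se = NA_real_, p_value = NA_real_,
             q_value = NA_real_, direction = NA_character_,
             n_used = n_used, fit_status = "ok",
             stringsAsFactors = FALSE)
}

# Prevalence floor shared by both models: detected in >= min_prevalence of
# samples and in >= min_studies distinct studies.
.passes_floor <- function(detected, study_id, min_prevalence, min_studies) {
  prev <- rowMeans(detected)
  n_stud <- apply(detected, 1, function(d)
    length(unique(study_id[d])))
  prev >= min_prevalence & n_stud >= min_studies
}

#' Per-species abundance model: CLR abundance with a study random intercept
#'
#' Fits, for each species, the linear mixed model
#' `clr ~ sex + age_bin + bmi_bin + continent + health + read_length_bin +
#' depth_bin + kit_bin + (1 | study_id)` and reports the sex coefficient
#' (female-positive coding: positive values read "female-enriched"), its
#' standard error and the Wald p-value.  Covariates constant in the data are
#' dropped from the formula.  Species below the prevalence floor are
#' flagged `skipped_low_prevalence`, fit failures `failed_convergence`;
#' neither is silently dropped.
#'
#' @param clr CLR-transformed matrix from [clr_transform()].
#' @param metadata covariate profile table from [bin_covariates()]; must
#'   include `study_id` and rows matching the matrix columns.
#' @param detected optional logical matrix (same shape as `clr`) marking
#'   which entries were observed; used for the prevalence floor.  When
#'   `NULL` every species is fit.
#' @param min_prevalence minimum fraction of samples a species must be
#'   detected in (default 0.10).
#' @param min_studies minimum number of studies a species must appear in
#'   (default 2).
#' @param single_study `"error"` (default) refuses single-study input;
#'   `"fixed"` drops the random intercept and fits ordinary least squares.
#' @return data.frame of association records, one row per species:
#'   `species_id`, `model`, `beta_sex`, `se`, `p_value`, `q_value` (NA
#'   until [adjust_fdr()]), `direction`, `n_used`, `fit_status`.
#' @export
fit_abundance_model <- function(clr, metadata, detected = NULL,
                                min_prevalence = 0.10, min_studies = 2L,
                                single_study = c("error", "fixed")) {
  single_study <- match.arg(single_study)
  mf <- .model_frame(metadata)
  if (!"study_id" %in% names(mf)) stopf("metadata lacks study_id")
  n_studies <- length(unique(mf$study_id))
  if (n_studies < 2 && single_study == "error")
    stopf(paste("single-study input: a study random intercept cannot be",
                "estimated; set single_study = 'fixed' to fit a",
                "fixed-effects model explicitly"))
  use_lmm <- n_studies >= 2

  terms <- .fixed_terms(mf)
  rec <- .assoc_record(rownames(clr), "abundance", ncol(clr))
  if (!is.null(detected)) {
    ok_floor <- .passes_floor(detected, mf$study_id, min_prevalence,
                              min_studies)
    rec$fit_status[!ok_floor] <- "skipped_low_prevalence"
  }

  rhs <- paste(terms, collapse = " + ")
  form <- if (use_lmm)
    stats::as.formula(paste("y ~", rhs, "+ (1 | study_id)"))
  else stats::as.formula(paste("y ~", rhs))
  mf$y <- 0

  base_fit <- NULL
  for (i in which(rec$fit_status == "ok")) {
    mf$y <- clr[i, ]
    res <- tryCatch({
      if (use_lmm) {
        if (is.null(base_fit)) {
          # singular fits (study variance estimated at 0) are legitimate
          base_fit <- suppressMessages(
            lme4::lmer(form, data = mf, REML = TRUE,
                       control = lme4::lmerControl(calc.derivs = FALSE)))
          fit <- base_fit
        } else {
          fit <- suppressMessages(lme4::refit(base_fit, newresp = clr[i, ]))
        }
        co <- lme4::fixef(fit)
        se <- sqrt(diag(as.matrix(stats::vcov(fit))))
      } else {
        fit <- stats::lm(form, data = mf)
        sm <- summary(fit)$coefficients
        co <- sm[, 1]; se <- sm[, 2]
      }
      j <- match("sexfemale", names(co))
      if (is.na(j)) stopf("sex term missing from fit")
      c(beta = unname(co[j]), se = unname(se[j]))
    }, error = function(e) NULL)
    if (is.null(res) || !is.finite(res["se"]) || res["se"] <= 0) {
      rec$fit_status[i] <- "failed_convergence"
    } else {
      z <- res["beta"] / res["se"]
      rec$beta_sex[i] <- res["beta"]
      rec$se[i] <- res["se"]
      rec$p_value[i] <- 2 * stats::pnorm(-abs(z))
      rec$direction[i] <- if (res["beta"] > 0) "female" else "male"
    }
  }
  rec
}

#' Per-species prevalence model: fixed-effects logistic regression
#'
#' Fits, for each species, `detected ~ sex + age_bin + bmi_bin + continent +
#' health + read_length_bin + depth_bin + kit_bin` with binomial family and
#' no random effects; `beta_sex` is the sex log-odds coefficient
#' (female-positive).  Species detected in every sample or in none (no
#' outcome variance), or below the prevalence floor, are flagged
#' `skipped_low_prevalence`; fits showing complete separation are flagged
#' `failed_convergence`.
#'
#' @param abundance relative-abundance matrix (species x samples).
#' @param metadata covariate profile table (see [fit_abundance_model()]).
#' @param detection_threshold abundance strictly above this counts as
#'   detected (default 0: any non-zero abundance is presence).
#' @inheritParams fit_abundance_model
#' @return data.frame of association records (see [fit_abundance_model()]),
#'   `model = "prevalence"`.
#' @export
fit_prevalence_model <- function(abundance, metadata,
                                 detection_threshold = 0,
                                 min_prevalence = 0.10, min_studies = 2L) {
  mf <- .model_frame(metadata)
  if (!"study_id" %in% names(mf)) stopf("metadata lacks study_id")
  detected <- abundance > detection_threshold
  terms <- .fixed_terms(mf)
  rec <- .assoc_record(rownames(abundance), "prevalence", ncol(abundance))

  prev <- rowMeans(detected)
  ok_floor <- .passes_floor(detected, mf$study_id, min_prevalence,
                            min_studies)
  rec$fit_status[!ok_floor | prev == 0 | prev == 1] <-
    "skipped_low_prevalence"

  X <- stats::model.matrix(
    stats::as.formula(paste("~", paste(terms, collapse = " + "))), mf)
  j <- match("sexfemale", colnames(X))
  for (i in which(rec$fit_status == "ok")) {
    y <- as.numeric(detected[i, ])
    separated <- FALSE
    res <- withCallingHandlers(
      tryCatch(stats::glm.fit(X, y, family = stats::binomial()),
               error = function(e) NULL),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", w$message))
          separated <<- TRUE
        invokeRestart("muffleWarning")
      })
    if (is.null(res) || !res$converged || separated) {
      rec$fit_status[i] <- "failed_convergence"
      next
    }
    beta <- res$coefficients[j]
    # covariance from the final IRLS weights
    se <- tryCatch({
      covm <- chol2inv(chol(crossprod(X * sqrt(res$weights))))
      sqrt(covm[j, j])
    }, error = function(e) NA_real_)
    if (!is.finite(beta) || !is.finite(se) || se <= 0 || se > 1e3) {
      rec$fit_status[i] <- "failed_convergence"
      next
    }
    z <- beta / se
    rec$beta_sex[i] <- beta
    rec$se[i] <- se
    rec$p_value[i] <- 2 * stats::pnorm(-abs(z))
    rec$direction[i] <- if (beta > 0) "female" else "male"
  }
  rec
}

#' Benjamini-Hochberg FDR across species, within each model family
#'
#' Fills `q_value` by applying the BH step-up procedure to the p-values of
#' successfully fit species, separately within the abundance and prevalence
#' families.  Records without a p-value keep `q_value = NA`.
#'
#' @param records association records from the model fitters (rows from
#'   several models may be concatenated).
#' @return The records with `q_value` filled; sorting by `p_value` within a
#'   family also sorts by `q_value`.
#' @export
adjust_fdr <- function(records) {
  if (nrow(records) == 0) return(records)
  for (m in unique(records$model)) {
    idx <- which(records$model == m & records$fit_status == "ok" &
                   !is.na(records$p_value))
    records$q_value[idx] <- stats::p.adjust(records$p_value[idx],
                                            method = "BH")
  }
  records
}
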