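#' Sample inclusion filters for metagenomic cohorts
#'
#' Applies the inclusion rules used for the multi-study meta-analysis.  A
#' sample is kept iff all of the following hold, checked in this order:
#' no current antibiotics use (an explicit `FALSE`; a missing value is
#' treated conservatively as use), mean read depth strictly above 20 million
#' base pairs, median read length strictly above 80 bases, stool body site
#' (case-insensitive exact match), and no model-adjustment covariate
#' missing.  The exclusion log records each dropped sample with the first
#' criterion it failed, in that order.  Extraction kit `"unknown"` is a
#' valid category, not missing data.
#'
#' @param metadata data.frame of sample metadata; must contain columns
#'   `sample_id`, `study_id`, `sex`, `age`, `bmi`, `continent`, `health`,
#'   `antibiotics_current`, `body_site`, `mean_read_depth`,
#'   `median_read_length`, `extraction_kit`.
#' @return A list with `kept` (the retained rows) and `exclusion_log`
#'   (data.frame with `sample_id`, `reason`).
#' @export
filter_samples <- function(metadata) {
  required <- c("sample_id", "study_id", "sex", "age", "bmi", "continent",
                "health", "antibiotics_current", "body_site",
                "mean_read_depth", "median_read_length", "extraction_kit")
  absent <- setdiff(required, names(metadata))
  if (length(absent))
    stopf("metadata is missing required column(s): %s",
          paste(absent, collapse = ", "))

  abx <- metadata$antibiotics_current
  fail_abx <- is.na(abx) | abx    # missing counts as use
  fail_depth <- !is.na(metadata$mean_read_depth) &
    metadata$mean_read_depth <= 2e7
  fail_len <- !is.na(metadata$median_read_length) &
    metadata$median_read_length <= 80
  fail_site <- is.na(metadata$body_site) |
    tolower(metadata$body_site) != "stool"
  covars <- c("sex", "age", "bmi", "continent", "health", "mean_read_depth",
              "median_read_length", "extraction_kit")
  fail_meta <- Reduce(`|`, lapply(metadata[covars], is.na))

  reason <- rep(NA_character_, nrow(metadata))
  reason[fail_meta] <- "missing_metadata"
  reason[fail_site] <- "non_stool_body_site"
  reason[fail_len] <- "short_read_length"
  reason[fail_depth] <- "low_read_depth"
  reason[fail_abx] <- "antibiotics"      # highest precedence, applied last

  keep <- is.na(reason)
  list(kept = metadata[keep, , drop = FALSE],
       exclusion_log = data.frame(sample_id = metadata$sample_id[!keep],
                                  reason = reason[!keep],
                                  stringsAsFactors = FALSE))
}

#' Bin sample covariates into the model's categorical profiles
#'
#' Maps continuous covariates onto closed vocabularies: age into
#' `<=1, >1-20, >20-40, >40-60, >60-80, >80` years; BMI into
#' `underweight (<=18.5), healthy (>18.5-25), overweight (>25-30),
#' obese (>30)`; median read length into `<100` / `>=100` bases; depth into
#' `<100M` / `>=100M`; extraction kit into `Qiagen`, `unknown`, `other`.
#' Boundary values follow the bracket notation: BMI 18.5 is underweight,
#' BMI 25 healthy, age 20 falls in `>1-20`, read length 100 in `>=100`.
#'
#' @param metadata data.frame of samples that already passed
#'   [filter_samples()]; `age` and `bmi` must be non-missing.
#' @return data.frame with one row per sample: `sample_id`, `study_id`,
#'   `sex`, `age_bin`, `bmi_bin`, `continent`, `health`, `read_length_bin`,
#'   `depth_bin`, `kit_bin`.
#' @export
bin_covariates <- function(metadata) {
  if (anyNA(metadata$age) || anyNA(metadata$bmi))
    stopf("age or BMI missing: run filter_samples() first")
  age_bin <- cut(metadata$age, c(-Inf, 1, 20, 40, 60, 80, Inf),
                 labels = c("<=1", ">1-20", ">20-40", ">40-60", ">60-80",
                            ">80"), right = TRUE)
  bmi_bin <- cut(metadata$bmi, c(-Inf, 18.5, 25, 30, Inf),
                 labels = c("underweight", "healthy", "overweight", "obese"),
                 right = TRUE)
  read_length_bin <- ifelse(metadata$median_read_length < 100,
                            "<100", ">=100")
  depth_bin <- ifelse(metadata$mean_read_depth < 1e8, "<100M", ">=100M")
  kit <- tolower(metadata$extraction_kit)
  kit_bin <- ifelse(kit == "qiagen", "Qiagen",
                    ifelse(kit == "unknown", "unknown", "other"))
  data.frame(sample_id = metadata$sample_id,
             study_id = metadata$study_id,
             sex = metadata$sex,
             age_bin = as.character(age_bin),
             bmi_bin = as.character(bmi_bin),
             continent = metadata$continent,
             health = metadata$health,
             read_length_bin = read_length_bin,
             depth_bin = depth_bin,
             kit_bin = kit_bin,
             stringsAsFactors = FALSE)
}
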