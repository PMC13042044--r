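#' Disease-status validation of candidate species in a case-control cohort
#'
#' For each candidate species, regresses its CLR-transformed relative
#' abundance on `disease + sex + treatment` (ordinary linear model, no
#' household pairing) and tests the disease term with a likelihood-ratio
#' test against the nested model without it (1 df).  BH-FDR is applied
#' across the tested candidate set only.  Species absent from the cohort
#' are recorded as untested rather than raising an error.
#'
#' @param cohort a [cohort_table()] whose metadata has `disease`, `sex`,
#'   `treatment` (and `edss` for [fit_severity_model()]).
#' @param species character vector of candidate species identifiers.
#' @param case_label metadata `disease` value identifying cases; a positive
#'   `beta_term` reads "enriched in cases".
#' @param pseudocount CLR pseudocount policy (see [clr_transform()]).
#' @return data.frame with one row per candidate: `species_id`, `model`,
#'   `beta_term`, `p_value`, `q_value`, `n_cases`, `n_controls`, `status`
#'   (`tested` / `untested`).
#' @export
fit_disease_model <- function(cohort, species, case_label = "MS",
                              pseudocount = "half_min_nonzero") {
  .fit_validation(cohort, species, focal = "disease",
                  case_label = case_label, pseudocount = pseudocount)
}

#' Severity validation: CLR abundance against the EDSS score
#'
#' Per candidate species, fits `clr ~ edss + sex + treatment` on the
#' samples with a non-missing EDSS score, treating EDSS as a continuous
#' linear predictor; the sign of `beta_term` is the severity direction.
#' The p-value is a 1-df likelihood-ratio test of the EDSS term.  With no
#' variance in EDSS every species is untested.
#'
#' @inheritParams fit_disease_model
#' @return As [fit_disease_model()], with `model = "severity"`.
#' @export
fit_severity_model <- function(cohort, species, case_label = "MS",
                               pseudocount = "half_min_nonzero") {
  .fit_validation(cohort, species, focal = "edss",
                  case_label = case_label, pseudocount = pseudocount)
}

.fit_validation <- function(cohort, species, focal, case_label,
                            pseudocount) {
  md <- cohort$metadata
  need <- c("disease", "sex", "treatment", if (focal == "edss") "edss")
  absent <- setdiff(need, names(md))
  if (length(absent))
    stopf("cohort metadata lacks column(s): %s",
          paste(absent, collapse = ", "))

  use <- if (focal == "edss") !is.na(md$edss) else rep(TRUE, nrow(md))
  md <- md[use, , drop = FALSE]
  clr <- clr_transform(cohort$abundance[, use, drop = FALSE], pseudocount)

  model_name <- if (focal == "disease") "disease" else "severity"
  out <- data.frame(species_id = species, model = model_name,
                    beta_term = NA_real_, p_value = NA_real_,
                    q_value = NA_real_,
                    n_cases = sum(md$disease == case_label),
                    n_controls = sum(md$disease != case_label),
                    status = "untested", stringsAsFactors = FALSE)

  dat <- data.frame(sex = md$sex, treatment = md$treatment)
  dat$x <- if (focal == "disease") as.numeric(md$disease == case_label)
           else md$edss
  covars <- c("sex", "treatment")
  covars <- covars[vapply(dat[covars],
                          function(v) length(unique(v)) >= 2, logical(1))]
  rhs_red <- if (length(covars)) paste(covars, collapse = " + ") else "1"
  form_full <- stats::as.formula(paste("y ~ x +", rhs_red))
  form_red <- stats::as.formula(paste("y ~", rhs_red))
  x_varies <- length(unique(dat$x)) >= 2
  if (!x_varies && focal == "edss") return(out)

  for (i in seq_along(species)) {
    sp <- species[i]
    if (!sp %in% rownames(clr)) next
    if (!x_varies) {
      # focal term constant: full and reduced models coincide
      out$beta_term[i] <- 0
      out$p_value[i] <- 1
      out$status[i] <- "tested"
      next
    }
    dat$y <- clr[sp, ]
    full <- stats::lm(form_full, data = dat)
    red <- stats::lm(form_red, data = dat)
    lrt <- max(0, 2 * (as.numeric(stats::logLik(full)) -
                         as.numeric(stats::logLik(red))))
    out$beta_term[i] <- unname(stats::coef(full)["x"])
    out$p_value[i] <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)
    out$status[i] <- "tested"
  }
  tested <- out$status == "tested"
  out$q_value[tested] <- stats::p.adjust(out$p_value[tested], method = "BH")
  out
}

#' Two-sided Fisher's exact test on a 2x2 count table
#'
#' Exact two-sided p-value by hypergeometric enumeration (via
#' [stats::fisher.test()]) together with the sample odds ratio
#' `(a*d)/(b*c)`, Haldane-corrected (0.5 added to every cell) when any cell
#' is zero.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return list with `odds_ratio` and `p_value`.
#' @export
fisher_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stopf("table must be 2x2")
  if (any(table < 0)) stopf("counts must be non-negative")
  if (any(table != round(table))) stopf("counts must be integers")
  p <- stats::fisher.test(table)$p.value
  t2 <- if (any(table == 0)) table + 0.5 else table
  or <- (t2[1, 1] * t2[2, 2]) / (t2[1, 2] * t2[2, 1])
  list(odds_ratio = or, p_value = p)
}
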