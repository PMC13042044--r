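#' Criteria for significant and high-confidence species selection
#'
#' @param fdr_cutoff FDR threshold for significance (strict `<`).
#' @param effect_quintile fraction of the universe forming the top effect
#'   tier by `|beta_sex|` (default 0.20, i.e. the top quintile).
#' @param fdr_quintile fraction forming the bottom significance tier by
#'   `q_value` (default 0.20, the bottom quintile).
#' @param quintile_universe `"significant_only"` (default) computes the
#'   quintile thresholds among species already significant at
#'   `fdr_cutoff`; `"all_tested"` uses every successfully fit species.
#' @return An object of class `selection_criteria`.
#' @export
selection_criteria <- function(fdr_cutoff = 0.05,
                               effect_quintile = 0.20,
                               fdr_quintile = 0.20,
                               quintile_universe = c("significant_only",
                                                     "all_tested")) {
  quintile_universe <- match.arg(quintile_universe)
  if (fdr_cutoff <= 0 || fdr_cutoff >= 1)
    stopf("fdr_cutoff must lie in (0, 1)")
  if (effect_quintile <= 0 || effect_quintile > 1 ||
      fdr_quintile <= 0 || fdr_quintile > 1)
    stopf("quintile fractions must lie in (0, 1]")
  structure(list(fdr_cutoff = fdr_cutoff,
                 effect_quintile = effect_quintile,
                 fdr_quintile = fdr_quintile,
                 quintile_universe = quintile_universe),
            class = "selection_criteria")
}

#' Significant species per model at an FDR cutoff
#'
#' @param records association records with `q_value` filled (see
#'   [adjust_fdr()]).
#' @param criteria a [selection_criteria()].
#' @return data.frame with columns `species_id`, `model`, `direction` for
#'   every record with `q_value < fdr_cutoff` (strict); may be empty.
#' @export
select_significant <- function(records, criteria = selection_criteria()) {
  sel <- records$fit_status == "ok" & !is.na(records$q_value) &
    records$q_value < criteria$fdr_cutoff
  out <- records[sel, c("species_id", "model", "direction"), drop = FALSE]
  rownames(out) <- NULL
  out
}

# Nearest-rank percentile: value at index ceiling(frac * n) of the sorted
# vector.  Boundary ties share the threshold, so all tied items pass.
.nearest_rank <- function(x, frac) {
  sort(x)[max(1L, ceiling(frac * length(x)))]
}

#' High-confidence species: top effect-size quintile and bottom FDR quintile
#'
#' Within the chosen universe (per model), computes the nearest-rank
#' threshold at the top `effect_quintile` of `|beta_sex|` and the bottom
#' `fdr_quintile` of `q_value`; a species is high-confidence in a model iff
#' its `|beta_sex|` is at or above the former and its `q_value` at or below
#' the latter.  The returned set is the union across models; species
#' high-confidence in both models with agreeing enrichment direction are
#' flagged `consistent_both`.
#'
#' @inheritParams select_significant
#' @return data.frame with one row per species in the union:
#'   `species_id`, `in_abundance_hc`, `in_prevalence_hc`, `consistent_both`,
#'   `direction` (abundance-model direction when available, otherwise
#'   prevalence).
#' @export
select_high_confidence <- function(records,
                                   criteria = selection_criteria()) {
  hc <- list()
  for (m in c("abundance", "prevalence")) {
    rm_ <- records[records$model == m & records$fit_status == "ok" &
                     !is.na(records$q_value), , drop = FALSE]
    if (criteria$quintile_universe == "significant_only")
      rm_ <- rm_[rm_$q_value < criteria$fdr_cutoff, , drop = FALSE]
    if (nrow(rm_) == 0) {
      hc[[m]] <- rm_[, c("species_id", "direction"), drop = FALSE]
      next
    }
    if (nrow(rm_) < 5)
      warning(sprintf("%s universe has only %d species; quintiles are %s",
                      m, nrow(rm_), "computed anyway"), call. = FALSE)
    beta_thr <- .nearest_rank(abs(rm_$beta_sex),
                              1 - criteria$effect_quintile)
    q_thr <- .nearest_rank(rm_$q_value, criteria$fdr_quintile)
    keep <- abs(rm_$beta_sex) >= beta_thr & rm_$q_value <= q_thr
    hc[[m]] <- rm_[keep, c("species_id", "direction"), drop = FALSE]
  }
  ids <- sort(unique(c(hc$abundance$species_id, hc$prevalence$species_id)))
  in_ab <- ids %in% hc$abundance$species_id
  in_pr <- ids %in% hc$prevalence$species_id
  dir_ab <- hc$abundance$direction[match(ids, hc$abundance$species_id)]
  dir_pr <- hc$prevalence$direction[match(ids, hc$prevalence$species_id)]
  data.frame(species_id = ids,
             in_abundance_hc = in_ab,
             in_prevalence_hc = in_pr,
             consistent_both = in_ab & in_pr &
               !is.na(dir_ab) & !is.na(dir_pr) & dir_ab == dir_pr,
             direction = ifelse(is.na(dir_ab), dir_pr, dir_ab),
             stringsAsFactors = FALSE)
}

#' Cross-model intersection counts of a high-confidence set
#'
#' @param hc high-confidence table from [select_high_confidence()].
#' @return data.frame with counts of `abundance_only`, `prevalence_only`
#'   and `both` species, overall and per enrichment direction.
#' @export
intersect_models <- function(hc) {
  cat_of <- function(a, p) ifelse(a & p, "both",
                                  ifelse(a, "abundance_only",
                                         "prevalence_only"))
  cats <- cat_of(hc$in_abundance_hc, hc$in_prevalence_hc)
  out <- expand.grid(category = c("abundance_only", "prevalence_only",
                                  "both"),
                     direction = c("female", "male", "all"),
                     stringsAsFactors = FALSE)
  out$count <- mapply(function(cat, dir) {
    sum(cats == cat & (dir == "all" | hc$direction == dir))
  }, out$category, out$direction)
  out
}
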