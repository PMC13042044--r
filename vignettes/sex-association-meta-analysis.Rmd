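---
title: "Sex-association meta-analysis of gut metagenomes: models, design and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sex-association meta-analysis of gut metagenomes: models, design and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

sexbiome asks a simple question of a large, heterogeneous collection of gut
shotgun metagenomes: which bacterial species differ between female and male
hosts, once the obvious confounders and the study-to-study batch structure
are accounted for — and do those species behave consistently when followed
into an independent disease cohort?  This vignette is the package's own
account of the statistical machinery, the choices that were genuinely open,
and what the synthetic-data tests do and do not establish.

## The data unit and quality control

Every model consumes a `cohort_table`: a species-by-sample matrix of
relative abundances (columns closed to 1) plus one metadata row per sample.
Samples enter the meta-analysis only if they pass, in order: no current
antibiotics use (a missing antibiotics record is treated as use — the
conservative reading, since the upstream repositories do not distinguish
"not recorded" from "no"), mean read depth strictly greater than 20 million
bp, median read length strictly greater than 80 bases, stool body site, and
complete model covariates.  The exclusion log stores the *first* failing
criterion per sample in that order, which makes QC runs diffable.

Continuous covariates are then binned into closed vocabularies (age in six
brackets with the boundary conventions `<=1`, `>1-20`, ...; BMI in the four
WHO-style brackets with 18.5 and 25 on the lower side of each boundary;
read length split at 100 bases; depth at 100M; extraction kit collapsed to
Qiagen / unknown / other).  Kit `"unknown"` is treated as a valid category
rather than missing data: it is a documented state of the source metadata,
not an absence.

## The two sex models

Abundances are centred log-ratio (CLR) transformed per sample,
$\mathrm{clr}_i = \ln(x_i + \varepsilon) - \tfrac1S\sum_j \ln(x_j +
\varepsilon)$, which maps compositions onto an unconstrained scale where
linear models are meaningful.  The pseudocount default is half the smallest
non-zero relative abundance in the table, applied uniformly; it is
configurable (`"none"` for strictly positive data, or any number) because
zero handling is the single most consequential free parameter in CLR
pipelines — see "Known limitations".

For each species two complementary models are fit:

* **Abundance** — a linear mixed model
  `clr ~ sex + age_bin + bmi_bin + continent + health + read_length_bin +
  depth_bin + kit_bin + (1 | study_id)`, with the study random intercept
  absorbing between-study technical and population offsets.  The reported
  effect is the sex coefficient under female-positive coding (positive =
  female-enriched), with its Wald normal p-value.  Covariates that do not
  vary in a given dataset are dropped from the formula automatically.
* **Prevalence** — a fixed-effects logistic regression of the detection
  indicator (`abundance > detection_threshold`, default threshold 0) on
  the same covariates, without random effects; presence–absence data
  across sparse studies make mixed logistic fits unstable, so the
  prevalence model is deliberately fixed-effects.

Species detected in fewer than 10% of samples or fewer than 2 studies are
flagged `skipped_low_prevalence` rather than silently dropped; this floor
is configurable and mirrors common practice in multi-cohort differential
abundance tools.  Logistic fits that trigger R's fitted-probability 0/1
warning, or that fail the IRLS convergence flag, are recorded as
`failed_convergence`.  This is a conservative policy: species detected in
nearly every sample often trip the warning without true separation and are
sacrificed; they sit at the boundary where the prevalence outcome carries
almost no information anyway.

Single-study input is refused by the abundance model unless
`single_study = "fixed"` is given explicitly, because a random intercept
cannot be estimated from one level and silently changing the model would
change the meaning of the results.

p-values are converted to q-values with Benjamini–Hochberg, applied
separately within each model family across species.

## Selection: significant, high-confidence, consistent

The significant set is `q < 0.05` (strict), partitioned by direction.  The
high-confidence set applies a quintile rule: within a universe of records
(by default the already-significant species of each model), a species must
sit in the top quintile of `|beta|` *and* the bottom quintile of `q` for
that model.  Percentiles use the nearest-rank rule, and boundary-tied
species all share the threshold value and are all included — this makes
selection deterministic and invariant to input order, at the cost of
occasionally admitting slightly more than 20%.  The per-model
high-confidence sets are united, and species high-confidence in both
models with agreeing direction are flagged `consistent_both`.

The universe choice (`significant_only` vs `all_tested`) was genuinely
open; `significant_only` is the default because stacking a stricter filter
on an already-significant list is the natural reading of "top hits using a
stricter cutoff", and the alternative remains selectable.

## Validation in a case-control cohort

Candidate species are followed into an independent case-control cohort
with disease status, an EDSS severity score (0 for controls), sex and
treatment status.  Per species, ordinary linear models on CLR abundance —
`clr ~ disease + sex + treatment` and `clr ~ edss + sex + treatment` — are
tested with a 1-df likelihood-ratio test of the focal term (the LRT
statistic is `n log(RSS0/RSS1)`; a constant focal term yields statistic 0
and p = 1).  Household pairing is deliberately *not* modelled: the target
formulas are unpaired, and adding a pair effect would change the estimand.
EDSS enters as a continuous linear term.  BH-FDR is applied across the
candidate set only, matching a focused validation rather than a
taxonomy-wide rescan.  Set-level enrichment of a species list against an
external annotation is a two-sided Fisher exact test on the 2×2 counts;
the odds ratio reported is the sample OR, Haldane-corrected (+0.5
everywhere) when a zero cell occurs.

## Mimicry scanning

The scanner slides a window the length of the anchor peptide along every
protein (step 1) and calls a hit when the window matches the anchor
*exactly* at every required position (default use: TCR-contact positions
2, 5, 7, 8 of a 9-mer).  Similarity is percent identity over the whole
window — the positional-regex framing implies identity, so no substitution
matrix is used — and hits strictly above the top-hit threshold (default
0.5) are flagged.  Windows are ungapped and fixed-register; non-standard
residues (X and friends) never match; proteins shorter than the anchor are
silently hit-free.  The anchor sequence is always an input, never
hard-coded.  Primer utilities compute inclusive amplicon lengths
(`reverse_end − forward_start + 1`) from 1-based genome coordinates.

## The synthetic-data generator

The generator exists so that every stage is testable against known ground
truth without downloading any real repository.  Latent per-sample log
abundances are additive: species baseline `N(0, 1.5)`, a per-study
per-species intercept `N(0, study_sd)` (species-specific, because a
study offset common to all species is removed by CLR centring and would be
invisible), the planted sex effect on designated species with alternating
signs, species-loaded covariate effects, and residual noise.  The latent
matrix is closed by softmax; detection is Bernoulli with probability
`logistic(logit(base_detection) + detection_slope · latent)`, and
undetected entries become zeros before renormalisation — so zeros arise
only through detection, matching the binomial prevalence model.

Key defaults and why:

| parameter | default | rationale |
|---|---|---|
| `n_studies`, `samples_per_study` | 8 × 100 | enough studies to estimate a random intercept; desk-scale total n |
| `n_species`, `n_sex_assoc` | 200, 20 | 10% planted, mirroring a sparse true-signal regime |
| `sex_effect_size` | 1.0 log-unit | a clearly detectable but not overwhelming shift |
| `study_sd` | 0.5 | between-study heterogeneity at half the residual SD |
| `residual_sd` | 1.0 | unit within-study noise |
| `base_detection` | 0.95 (0.98 validation) | prevalent-species panels retained by a 10% floor; validation candidates are by construction prevalent |
| `detection_slope` | 0.5 (0.25 validation) | abundance–detection coupling present but moderate |

The detection defaults deserve a note.  Because the default pseudocount is
half the *global* minimum non-zero abundance, an undetected entry maps to
an extreme negative CLR value.  If detection is strongly coupled to the
latent abundance, a planted sex effect moves detection rates between the
sexes and the zeros then amplify the measured CLR effect well beyond the
planted latent unit — at which point "effect size 1.0" no longer means
anything precise.  The defaults keep this distortion small so that one
planted latent log-unit reads as approximately one CLR unit, which is what
makes parameter-recovery statements well-defined.  The recovery *unit*
test for the abundance fitter goes one step further and sets
`detection_slope = 0`, so the planted effect is exactly the estimand.

The validation generator emits one cohort at the emulated case-control
scale (576 cases / 576 controls — the size of the real consortium cohort
it imitates) with EDSS drawn uniformly on 0–7 in half-point steps for
cases and 0 for controls.  One sample per synthetic individual is emitted;
repeated sampling of individuals, present in the real repositories, is not
modelled.

Proteomes are uniform random sequences over the 20 standard residues;
planted proteins receive a constructed window (anchor residues at the
required positions, random elsewhere) at a random offset, and *all*
proteins are rejection-sampled to contain no accidental match beforehand,
so the planted count is exact by construction.

## What the tests establish — and what they cannot

Problem sizes were chosen so the full suite runs in a few minutes: the
discovery recovery check uses ten seeds of the default 8 × 100 × 200
cohort; null calibration uses five seeds of the same and twenty
permutation seeds of the 576/576 validation cohort; the scanner is checked
against an exhaustive double-loop oracle on fifty 200-protein proteomes.

Passing these tests shows that the estimators recover what the generator
plants, that type-I error is nominal under the generator's null, and that
the combinatorial stages (QC, selection, scanning) are exactly correct.
It does *not* show that the pipeline recovers the truth about real gut
metagenomes: the generator has no phylogenetic correlation between
species, no realistic rank-abundance shape, no correlated covariates
(age, BMI, continent are sampled independently), no repeated samples per
individual, and zeros arise only from detection, never structurally.

## Known limitations and numerical notes

* **Compositional spillover.**  Planting a positive effect on a few
  species necessarily depresses the CLR values of all others in the
  affected samples.  At large n this closure artifact becomes detectable:
  in the bundled validation analysis, five planted disease effects of
  +1.0 drag a dozen unplanted species below FDR 0.05 with small negative
  coefficients.  This is a property of CLR-based differential abundance
  generally, not of this implementation.
* **Gaussian LRT at small n.**  With pseudocounted zeros the CLR values
  are heavy-tailed, and the chi-square LRT is visibly liberal in small
  cohorts (≈6–7% at nominal 5% for n = 200); at the default 576/576 scale
  it is nominal.  Permutation nulls in the test-suite are therefore run at
  the emulated cohort scale.
* **Mixed-model p-values** are Wald normal; with 800 samples and 8 study
  levels the normal approximation is excellent (the null KS check passes),
  but for very small cohorts a Satterthwaite or LRT option would be the
  next addition.
* **Ties and determinism.**  Nearest-rank percentiles, stable
  `(protein_id, offset)` hit ordering, and seed-derived sub-streams make
  every stage a pure function of (inputs, config, seed); run manifests
  record an md5 of the analytic config (output paths excluded).
* The sex-relabel invariance of the mixed model holds to ~1e-8 — the REML
  optimiser's stopping tolerance, not exact algebra as in the fixed-effects
  models.
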