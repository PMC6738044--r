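---
title: "Discovering and validating urinary peptide panels for significant prostate cancer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering and validating urinary peptide panels for significant prostate cancer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(uripanel)
library(dplyr)
```

## The problem

Most prostate cancers found at biopsy are indolent (Gleason score 6),
yet the diagnostic pathway — PSA testing followed by multi-core biopsy —
cannot separate them well from clinically significant disease
(Gleason ≥ 7). Urinary peptidomics offers a non-invasive alternative:
capillary electrophoresis coupled to mass spectrometry (CE–MS) resolves
thousands of endogenous peptides per urine sample, each characterised by
molecular mass (kDa), normalised migration time (min) and signal
intensity (AU). A panel of differentially excreted peptides, combined by
a support vector machine (SVM), can be scored against a fixed cutoff to
flag patients likely to harbour significant cancer before the biopsy
decision.

`uripanel` implements that workflow end to end as composable,
pipe-friendly functions: a synthetic cohort generator with known ground
truth, internal-standard normalisation and log transformation,
stability-filtered Wilcoxon/Benjamini–Hochberg biomarker discovery, SVM
panel scoring with a discovery-set cutoff, and a validation /
clinical-utility suite (ROC with DeLong variance, exact binomial
intervals, Kruskal–Wallis across Gleason strata, logistic nomograms,
decision-curve analysis). Because patient-level CE–MS cohorts of this
kind are not publicly deposited, the generator is a first-class module:
every downstream stage is exercised, and its error rates measured,
against cohorts whose truth is known.

## Data model

A `peptide_matrix` holds samples × peptides intensities in AU with `0`
meaning *not detected*; peptide metadata (mass, migration time,
internal-standard flag) travels with it, and a scale tag enforces the
processing order `raw → normalised → log`. On disk the matrix is a wide
UTF-8 TSV with peptides as rows (peptide counts dwarf sample counts);
in memory rows are samples, which is what the statistics want. The
clinical annotation is a plain tibble; the binary outcome (`sig` =
Gleason ≥ 7) is always derived from the Gleason stratum, and rows with
PSA ≥ 15 ng/ml are rejected at validation because the modelled cohort
is defined by PSA < 15 ng/ml at biopsy.

Non-detects are encoded `0` at every scale — there is no NaN sentinel —
and every rank-based statistic treats them as left-censored values tied
below all detected values. That convention is the standard conservative
choice for detection-limited data, and it makes the 70% detection
filter unambiguous. One corner is worth stating: after the natural-log
transform a *detected* intensity of exactly 1 AU would also map to 0.
`log_transform()` warns when that collision can occur; at realistic AU
scales (the generator's default detected log-intensity is around 9
log-AU) it never does.

## The synthetic cohort generator

`simulate_cohort()` draws what the analysis assumes and nothing more:

* **Intensities.** Detected log-intensities are normal around a
  per-peptide baseline (`base_log_mean = 9`, between-peptide SD 1,
  within-peptide SD `base_log_sd = 1` log-AU). Planted markers add a
  signed effect to cases, additive on the log scale (multiplicative on
  AU), which is how the downstream log-scale statistics expect effects
  to act.
* **Censoring.** Each cell is independently set to 0 with one minus its
  detection probability; background peptides draw detection from
  `detection_prob_range = (0.4, 0.98)`, planted markers default to
  0.95, internal standards to 0.995. An intensity-linked (logistic in
  the latent log-intensity) censoring mode exists for sensitivity
  analyses, but independent censoring is the default: no missingness
  mechanism is published for this data type, and the independent model
  is the simplest one that exercises the frequency rule.
* **Acquisition scale.** Every sample gets a multiplicative factor
  (log-SD 0.25) that internal-standard normalisation is supposed to
  remove — so normalisation is genuinely tested, not decorative.
* **Clinical covariates.** Ages, PSA, DRE, prior biopsies, prostate
  volume (with ~12% missingness), 5-ARI use and creatinine are drawn
  with medians, spreads and group differences typical of a large
  biopsy cohort: cases older (median 68 vs 63 y), higher PSA (median
  6.1 vs 5.1 ng/ml), fewer prior biopsies, smaller prostates. An
  `external_risk` column emulates an external risk calculator with a
  planted binormal AUC of 0.69. Covariates are independent of peptides
  by default because the pipeline treats them separately.
* **Reproducibility.** One user seed feeds fixed-offset sub-streams
  (intensities, detection, covariates, split, stability runs), so
  extending one generator never perturbs another.

`simulate_study_scale()` freezes the preset used throughout the tests:
823 samples (146 cases / 677 controls), 29 internal standards, 19
planted markers at 1.5 log-AU, 1000 peptide features. Real CE–MS urine
profiles contain several thousand peptides; 1000 keeps repeated-seed
simulation studies fast while leaving a realistic multiplicity burden.

What the generator does **not** emulate: migration-time drift, batch
effects, covariate–peptide correlation (off by default), heavy-tailed
intensity noise, or structured missingness. Tests passing on these
cohorts therefore demonstrate that the machinery is correct and
well-calibrated under its own assumptions — not that any particular
real-world performance level will be attained.

## Preprocessing

**Normalisation.** Twenty-nine endogenous collagen fragments that are
largely disease-invariant serve as internal standards. Each standard's
reference level is its median detected intensity across samples; each
sample's factor is the median, over the standards detected in that
sample, of reference/observed; detected intensities are multiplied by
the factor and zeros stay zero. The median-of-ratios form is robust to
individual standard dropout. One subtlety: with a *data-derived*
reference the normalised scale retains a small global indeterminacy, so
"normalising twice" is only approximately a no-op. Against a *fixed*
reference the operation is exactly idempotent and exactly cancels any
per-sample multiplicative distortion, which is why
`fit_normalisation()` accepts a `reference` argument and the package's
invariant tests pin these properties at 1e-12.

**Split.** `stratified_split()` implements the 2/3–1/3 rule per outcome
class: `round(fraction · n_class)` samples (half away from zero) drawn
without replacement into discovery. With 146 cases and 677 controls
this yields 97/451 discovery — the realised counts are *reported*, not
assumed, since other allocation conventions round differently.

## Discovery

Per peptide, case and control log-intensities are compared with the
two-sample Wilcoxon rank-sum test: exact enumeration of the U null
distribution for untied samples up to a combined n of 12, otherwise the
normal approximation with tie and continuity corrections. Peptides
first pass a detection filter — at least 70% detection in at least one
outcome group, boundary inclusive — and p-values are Benjamini–Hochberg
adjusted *within the filtered family* (the family must be explicit
because it sets the multiplicity m; filtering before testing is the
default and a raw-p mode is available via `use_adjusted = FALSE`).

The stability analysis repeats all of this five times on random
stratified subsamples that each exclude 30% of the discovery set;
stratification matters because cases are only ~18% of the cohort and an
unstratified 30% exclusion risks class collapse. Only peptides
significant (adjusted p < 0.05) in **all** runs enter the panel;
directions (up/down in significant cancer, from censored medians, ties
breaking to "up") and reported statistics come from the full discovery
set. Although procedures like this are sometimes loosely called
permutation analyses, what is described and implemented is subsampling
(random exclusion), so the package names it a stability analysis.

Under the null (no planted markers) the unanimity rule stacked on BH is
at least as strict as a single BH pass, and the acceptance suite
verifies empirically that ≥95% of null cohorts return an empty panel
and that the mean false discovery proportion stays ≤ 0.05.

## Classification

`train_svm()` freezes a feature pipeline on the discovery set only:
censored zeros become that peptide's minimum detected discovery
log-intensity minus `zero_offset` (default 1 log-unit — the SVM needs a
numeric floor and it must be explicit), features are centred and scaled
by discovery constants, and an SVM (radial basis by default, C = 1,
γ = 1/n_panel; linear available) is fit with each panel peptide one
dimension. The upstream reference software for this workflow does not
publish its kernel or tuning, so the defaults here are frozen and
explicit rather than silently tuned; an optional grid search would be
an extension, not a default, and is deliberately not implemented.
Scores are oriented so higher = more case-like. A Platt-type logistic
map fitted on discovery scores supplies the probabilities that
decision-curve analysis needs (the score-to-risk mapping must be chosen
somewhere; a one-pair logistic map is the minimal monotone choice).

The decision cutoff is established on the discovery set:
`"youden"` (default) maximises sens + spec − 1 over score midpoints
with ties resolved toward the lower cutoff (sensitivity-first, matching
the clinical intent of a rule-out test), or `"target_sensitivity"`
picks the largest cutoff achieving a required discovery sensitivity.
Cutoffs reported for proprietary CE–MS classifiers of this kind (for
instance −0.07) are illustration constants only: they belong to
undisclosed decision functions and are never asserted by any test
here.

## Validation and clinical utility

* `roc_curve()` stores the full threshold curve; the AUC is the
  tie-aware Mann–Whitney statistic and equals the trapezoid of the
  stored curve to 1e-12; the variance is DeLong's, with a normal CI
  clipped to [0, 1]. "Exact binomial" intervals for sensitivity and
  specificity are Clopper–Pearson; the positive call is score ≥ cutoff
  (ties to positive).
* `delong_test()` compares correlated AUCs through placement-value
  covariances; a zero-variance difference returns p = 1 by convention.
* `kruskal_wallis()` (tie-corrected, chi-squared reference) compares
  classifier scores across Gleason strata; with two groups it equals
  the squared tie-corrected rank-sum deviate, which the tests check
  numerically.
* `cohort_summary()` reproduces baseline-table bookkeeping: medians/IQR
  with Mann–Whitney p for continuous variables, counts/percentages with
  chi-squared p (no Yates correction by default; flag available) for
  categorical ones, pairwise-complete handling of prostate volume with
  reported n, and Gleason-stratum percentages computed within the same
  outcome. `cohort_from_counts()` reconstructs a per-sample fixture
  from printed marginal counts so that count-derived percentages can be
  verified exactly; its default counts contain one internal
  inconsistency faithfully inherited from its source structure (the
  control-group prior-biopsy cells sum to 667, not 677), resolved by
  treating group totals and the quoted percentages as authoritative.
* `fit_logistic()` / `build_nomogram()` give odds ratios, Wald tests,
  separation and collinearity diagnostics, and an inverse-logit risk
  function combining biomarker score, PSA and age.
* `decision_curve()` computes net benefit
  NB(p_t) = TP/n − (FP/n)·p_t/(1−p_t) against treat-all and treat-none
  over a default grid of 0.01–0.50 by 0.01 — the clinically relevant
  low-threshold range for a biopsy decision. `compare_models()` runs
  pairwise DeLong tests and a joint decision curve, and automatically
  excludes 5-ARI-treated patients from any comparison involving PSA,
  reporting the reduced n.

## A worked run

```{r pipeline, eval = FALSE}
sim <- simulate_study_scale(seed = 1)
res <- run_panel_pipeline(sim$matrix, sim$samples, seed = 1)
res
glance(res)

# how much of the planted truth was found?
mean(res$panel$peptide_id %in% sim$truth$markers$peptide_id)

# comparators on the validation set
val <- sim$samples |>
  dplyr::filter(sample_id %in% split_ids(res$split, "validation")) |>
  dplyr::mutate(panel_score = res$scored_validation$score)
compare_models(val, c("panel_score", "psa", "external_risk"))
```

(The chunk is not evaluated at build time; `scripts/acceptance.R` runs
exactly this computation and records its numbers.)

## Numerical choices and degenerate inputs

* Rank statistics use midranks; the exact Wilcoxon path requires no
  ties and combined n ≤ 12 (configurable), two-sided p = doubled
  smaller tail capped at 1.
* All-tied inputs: rank-sum and Kruskal–Wallis return p = 1; ROC on a
  constant score gives AUC 0.5.
* Empty discovery panels are a warning-level result — downstream
  training refuses them with a clear error rather than fabricating a
  classifier.
* Perfect separation in logistic fits is flagged, not hidden; rank
  deficiency is an error naming the collinear terms.
* Net-benefit grids must stay strictly below 1 (the odds weight
  diverges); DCA rows for treat-all/treat-none are computed from their
  closed forms.
* The problem sizes used by the test-suite simulation studies — 100
  null cohorts of 400 × 300, twenty study-scale cohorts of 823 × 1000,
  100 binormal coverage replicates — were chosen as the smallest
  designs that give the binomial error of each checked proportion a
  comfortable margin against its threshold.

## Interfaces

All user-facing functions take a data frame (or `peptide_matrix`)
first and return tibbles, so stages chain with the pipe; fitted objects
expose `tidy()`/`glance()` and result types have `autoplot()` methods.
File exchange is plain TSV (`read_peptide_matrix()`,
`read_sample_table()`, `write_report()`); every tunable lives in
`pipeline_config()`, overridable from YAML via
`read_pipeline_config()`. The package deliberately ships no shell
entry point: its users drive analyses from R, and
`scripts/acceptance.R` demonstrates the full scripted workflow.

## Limitations

The pipeline starts at deconvoluted peak lists — raw spectra, charge
deconvolution, migration-time recalibration and MS/MS identification
are out of scope. No covariate-adjusted peptide testing, batch
correction, effect shrinkage or optimism-corrected (bootstrap) internal
validation is provided. Published external risk calculators are
represented only as a user-supplied probability column. And the
simulation-based error rates quoted above are properties of the
generator's assumptions; transport to real cohorts requires external
validation, as it does for any biomarker model.
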