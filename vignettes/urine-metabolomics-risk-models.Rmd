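---
title: "Urine metabolomic marker panels for prostate cancer risk models: methods and design"
author: "uroMetPanel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Urine metabolomic marker panels: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Men with an elevated prostate cancer (PC) risk — typically PSA ≥ 4 ng/mL —
face a biopsy decision under substantial uncertainty: serum PSA separates
benign from malignant poorly, and it barely separates indolent from
clinically significant disease (sPC). A urine GC-MS metabolomic profile,
combined with five routine clinical factors (age, serum PSA, family history,
previous negative biopsy, abnormal DRE), can stratify that risk before
biopsy. This package implements the complete analysis machinery for building
and judging such models:

1. **Preprocessing** of a peak table (samples × metabolite features) into
   analysis-ready log intensities.
2. **Marker selection** by a resampling-stability ensemble of logistic
   models with AIC backward elimination.
3. **Endpoint models** dichotomizing the NCCN risk strata four ways.
4. **Clinical utility**: ROC/AUC with DeLong machinery, fixed-sensitivity
   operating points, enrollment-reweighted biopsy avoidance, and decision
   curve analysis.
5. A **synthetic cohort generator** reproducing the statistical structure
   this analysis assumes, so every stage is testable without patient data.

# Data model

A `MetaboCohort` (a `SummarizedExperiment`) holds the raw peak areas
(features × samples, `NA` = peak not detected), per-sample urine creatinine,
and the subject table. Risk groups use the NCCN-derived labels benign, VLR,
LR, FIR, UIR, HR, VHR, mPC; throughout the analysis they are merged into six
ordered strata (benign, VLR/LR, FIR, UIR, HR/VHR, mPC), mirroring how cohort
composition tables report them.

The four endpoints (`endpointSpec()`):

* **Model I** — benign (0) vs any PC (1);
* **Model II** — benign + VLR/LR vs FIR…mPC (sPC for men with a long life
  expectancy);
* **Model III** — benign + VLR/LR + FIR vs UIR…mPC (shorter life
  expectancy);
* **Model GS** — benign or Gleason sum < 7 vs Gleason sum ≥ 7.

# The synthetic cohort generator

`generateCohort(cohortConfig())` emulates the study conditions the analysis
expects:

* **Cohort composition.** Defaults fix the training cohort at 603 subjects
  (110 / 74 / 74 / 105 / 202 / 38 across the six strata) and the validation
  cohort at 325 (158 / 26 / 25 / 34 / 66 / 16), i.e. a benign-depleted
  training set and a validation set restored to roughly the at-risk
  population's composition. The enrollment-pool weights used for biopsy
  avoidance default to (0.520, 0.087, 0.074, 0.110, 0.183, 0.026).
* **Peak areas** are log-normal per feature (multiplicative MS noise);
  planted marker effects are additive on the log scale, expressed in units
  of the feature's log-SD, with monotone severity profiles. Default
  profiles alternate between "depressed in all cancer strata"
  (monopalmitin-like) and "rising with severity"
  (1-stearoyl-rac-glycerol-like).
* **Missingness** is a point mass at "not detected", with per-feature
  detection probability spread on the logit scale and a within-feature
  intensity dependence (weaker peaks drop out more often), emulating
  detection limits. The defaults (`missingRateBase = 0.87`,
  `presenceSdLogit = 1.5`) were calibrated once, by simulation, so that
  roughly 170 of 1,941 raw features pass the 60% presence filter —
  reproducing the scale of the quality-controlled feature set the analysis
  operates on.
* **PSA** is log-normal with location increasing in severity, so clinical
  factors carry real signal and combined models genuinely outperform
  panel-only models, as in the study.
* **Urine creatinine** is log-normal around 100 mg/dL; no published
  distribution was available to calibrate against, so these values are
  plausible but uncalibrated (they only exercise the normalization
  arithmetic).
* One master seed drives separate sub-seeds for subjects, feature
  parameters, intensities and missingness, so regeneration is stable.

What the generator does **not** emulate: chromatographic artefacts, batch
effects beyond total-area scaling, inter-metabolite correlation structure,
or any real metabolite identities. Passing tests therefore demonstrate that
the *machinery* behaves correctly and is calibrated (no selection-induced
optimism, recoverable planted effects), not that any particular AUC is
attainable on real patients.

# Preprocessing

Fixed order: presence filter → normalization → imputation → log transform.

* **Presence filter**: a feature is kept iff observed in *strictly more*
  than 60% of the samples of at least one risk stratum ("more than 60%" is
  read as a strict inequality). The filter is a data-acquisition quality
  screen, so it is applied to the pooled cohort before the
  training/validation split.
* **Normalization**: the published procedure normalizes "by both urine
  creatinine and total peak area". Whether that means sequentially, in
  parallel models, or averaged is not stated; the default here applies both
  corrections sequentially (divide by total peak area, then by creatinine),
  and both single modes are selectable. Total peak area refers to the whole
  acquisition, so `preprocessCohort()` computes it before the feature
  filter.
* **Imputation and transform**: the publication is silent on missing-value
  handling; half-minimum imputation per feature followed by a natural-log
  transform are the metabolomics conventions adopted here, both
  config-switchable.

# The logistic engine

All stages share one fitter, `fitLogistic()`: iteratively reweighted least
squares with step halving, run to a gradient max-norm below 1e-8 or 100
iterations; Wald standard errors from the final observed information.
Because the score also vanishes when slopes diverge under (quasi-)complete
separation, separation is detected by a scale-invariant criterion (any slope
moving the logit by more than 10 per predictor SD); separated or
non-convergent fits are refit with a ridge penalty of 1e-4 on slopes (never
the intercept) and flagged. The ridge fallback was chosen over Firth
correction for simplicity and transparency; the penalty and the flag are
recorded in the fit. The log-likelihood and AIC (2k − 2·lnL, k counting the
intercept) are always the *unpenalized* quantities evaluated at the
returned estimate.

One consequence: under separation the penalized Wald statistic is
meaningless (the Hauck–Donner effect). The univariate screen therefore
scores separation-flagged single-feature fits by their likelihood-ratio
p-value instead, so a perfectly separating feature is kept rather than
absurdly excluded. The multivariable pruning stage keeps plain Wald p-values
(its fixed-point contract is defined in terms of them).

# Marker selection

`selectMarkerPanel()` reproduces the published ensemble:

1. **Resampling**: outcome-stratified K-fold cross-validation (K = 5),
   reshuffled for 20 rounds → 100 fold-training sets (stratification is a
   design choice; the publication says only "K-fold", but unstratified
   folds can lose a class at these prevalences).
2. **Per fold-training set**: univariate logistic screen (exclude p > 0.1)
   → AIC backward elimination (greedy: remove the feature whose removal
   lowers AIC most, stop at the nadir) → multivariable pruning (iteratively
   drop the worst feature with joint-model Wald p > 0.1). If the univariate
   screen keeps more features than a tenth of the fold-training sample
   size, the list is pre-truncated to the best n/10 by univariate p so the
   joint fits stay well-posed.
3. **Recurrence ranking**: the top 75% of the 100 candidate models —
   ranked by held-out (testing-fold) AUC; the publication does not name its
   ranking statistic, and training AIC is available as a config option —
   vote with their retained sets; the top 30 recurring metabolites are
   ranked by count, ties broken by mean full-cohort univariate p, then
   feature id (determinism).
4. **Panel sizing**: nested logistic fits of the top-1 … top-30 features on
   the full training cohort; the panel size is the AIC nadir (ties to the
   smaller panel). The nadir search is run on the full training cohort per
   endpoint — whether the original analysis ran it within folds is not
   stated, and the full-cohort reading matches "cumulative" AIC over one
   nested sequence.

Selection runs independently per endpoint (four separate panels), and
validation subjects can never enter a selection fold: the ensemble carries
an explicit guard that aborts if a forbidden id appears in its input.

# Fitted models and evaluation

For each endpoint, four predictor sets are fit on the training cohort and
evaluated on both cohorts: the five clinical factors alone, the marker
panel alone, panel + PSA, and the combined model (panel + all five
factors). Combined models refit all coefficients jointly; the alternative —
freezing the panel logit as an offset — is not what single combined AUCs
suggest, and no offset procedure was published. PSA enters untransformed by
default (`logPsa = TRUE` switches to log-PSA).

Evaluation conventions:

* Higher score = more likely positive; test-positive iff score ≥ threshold.
* AUC is the tie-corrected concordance probability; its variance and the
  paired AUC comparisons use DeLong's placement components, with p = 1
  returned for a zero-variance zero difference.
* The Youden operating point maximizes sensitivity + specificity − 1 over
  observed thresholds, ties resolved toward higher specificity.
  Fixed-sensitivity points (90%, 95%) take the *highest* threshold with
  sensitivity at or above target, maximizing specificity subject to the
  constraint.
* **Biopsies avoided** renormalizes the cohort to the enrollment
  composition: each stratum contributes its weight times the fraction of
  its subjects that are endpoint-negative *and* test-negative. For strata
  that are entirely endpoint-negative this is weight × specificity (0.520 ×
  0.92 ≈ 48% for a benign-vs-cancer model at 92% specificity); for Model
  GS, where cancer strata mix Gleason < 7 and ≥ 7, the stratum weight is
  implicitly allocated by its observed negative-class share — the only
  reading bounded by the total weight of endpoint-negative strata.
* Cohort-comparison tests are the uncorrected Pearson chi-square (validated
  against published 2×2 p-values to four decimals, which rules out the
  Yates correction) and the tie- and continuity-corrected normal
  approximation to the Mann–Whitney U.

# Decision curve analysis

Net benefit follows the standard Vickers–Elkin form
NB(p_t) = TP/n − (FP/n)·p_t/(1−p_t), evaluated over a default grid of
threshold probabilities 0.01–0.50 (covering the 10% focal point used for
reporting biopsies avoided per 1,000), against biopsy-for-all and
biopsy-for-none references. Interventions avoided per 1,000 at-risk
subjects use 1000 × (NB_model − NB_all) × (1−p_t)/p_t. A structural
consequence reproduced by the synthetic cohorts: the benign-richer
validation cohort shows a larger net-benefit gap over biopsy-for-all than
the cancer-enriched training cohort at the same p_t.

# Numerical and degenerate-input choices

* Presence filter: strict `>` at the boundary; empty-stratum inputs are a
  configuration error.
* Half-minimum imputation cannot exceed any observed value by
  construction; a feature with no observed values after filtering is an
  internal-consistency error.
* Backward elimination tolerates non-convergent candidate fits via the
  ridge fallback and never aborts; an all-noise model may legitimately
  collapse to intercept-only.
* Ties in the AIC nadir go to the smaller panel; ties in recurrence
  ranking are broken deterministically (mean univariate p, then id).
* Degenerate DeLong comparisons (zero variance) return p = 1 when the
  difference is 0 and p = 0 otherwise, flagged.

# Problem sizes used by the test suite

The packaged tests run the full structure at reduced scale so the suite
stays fast: calibration checks use 300-feature cohorts at the published
cohort sizes with 10-model ensembles over 40 seeds (null cohorts must keep
the validation AUC of the selected panel inside [0.4, 0.6]; cohorts with
ten ±0.8 SD planted markers must recover at least 8 of them in ≥ 80% of
seeds), while the ensemble-cardinality check runs the full 20 × 5 = 100
models. The acceptance script (`scripts/acceptance.R`) runs the complete
default configuration — 1,941 features, 603 + 325 subjects, 100-model
ensembles, all four endpoints.

# Known limitations

* Metabolite identities are synthetic; nothing here validates biology.
* The generator's independence across features understates the
  collinearity of real metabolomic panels, which makes panel-size nadirs
  on real data likely smaller than on synthetic data.
* Firth-corrected fits, lasso/elastic-net selectors, nested
  cross-validation of the whole pipeline, and bootstrap AUC intervals are
  deliberately out of scope.
* The urine creatinine distribution is plausible, not calibrated.

# A minimal run

```{r example}
library(uroMetPanel)
cfg <- pipelineConfig(
  cohort = cohortConfig(nFeatures = 300, seed = 7),
  selection = selectionConfig(rounds = 2, seed = 7),
  endpoints = c("I", "II"), seed = 7)
report <- runPipeline(cfg)
report
writeReport(report, "output")
```
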