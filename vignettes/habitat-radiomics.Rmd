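---
title: "Multi-habitat MRI radiomics: models, defaults, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-habitat MRI radiomics: models, defaults, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The analysis in one paragraph

Habitat imaging treats the tumor volume delineated on each MRI sequence as
a distinct *habitat*. For every patient, nine co-registered sequences
(sagittal/axial T2, axial T1, diffusion b=0/b=800, ADC, and three
contrast-enhanced T1 orientations) each contribute one habitat, and each
habitat contributes 114 three-dimensional radiomic descriptors. A
three-step selection — reproducibility (ICC against a second radiologist's
re-segmentation), redundancy pruning (pairwise Pearson correlation), and
LASSO logistic regression — compresses each habitat's 114 features into a
sparse linear *habitat signature*. A grid search over logistic regression,
radial-kernel SVM, and random forest, over signature subsets optionally
augmented with the clinical covariate block, picks the fused *radiomic
model* by mean accuracy under repeated stratified 3-fold cross-validation
of the training set. The model's output probability (the radiomic score)
is then evaluated for discrimination (ROC/AUC with DeLong 95% CIs), a
Youden-optimal cutoff with accuracies, calibration (Hosmer–Lemeshow),
inter-radiologist reliability (score ICC and a paired DeLong test), and
stability under repeated random train/test splits.

```{r}
library(habitomics)
cfg <- pipeline_config(
  cohort = cohort_config(n_patients = 120, seed = 1),
  train_size = 60, seed = 42)
report <- run_pipeline(cfg)
print(report)
```

## The feature inventory

Each habitat vector has exactly 114 entries: 14 shape descriptors of the
mask, and 7 histogram + 7 GLCM + 6 GLRLM descriptors on each of five
images — the z-normalized original (`X`) and its four slice-wise
undecimated Haar sub-bands (`XLL`, `XLH`, `XHL`, `XHH`). Names follow the
field's convention (`X_GLRLM_LRHGLE`, `XLL_H_skewness`, bare `Surface_area`).
Across nine habitats a patient contributes 9 × 114 = 1026 features.

Key numerical conventions, chosen where the underlying procedure is
underdetermined and fixed package-wide:

* **Intensity normalization** is z-scoring over the *whole volume* (not the
  ROI), so tumor-to-background contrast survives normalization.
* **Discretization** uses a fixed bin count (default 32), equal-width over
  the in-mask intensity range, recomputed per image (original and each
  sub-band). Fixed bin counts are the usual choice for intensities that
  have already been z-scored and for sub-band images whose scales differ.
* **Texture aggregation**: GLCM and GLRLM matrices are built per direction
  at distance 1 for the 13 unique 3D directions; descriptors are computed
  per direction and averaged unweighted. GLCMs count each in-mask pair
  symmetrically and are normalized to sum 1; GLRLM runs are maximal streaks
  of equal gray level along consecutive in-mask voxels (leaving the mask
  ends a run).
* **Wavelet sub-bands** are single-level 2D Haar, computed slice-wise in
  the axial plane, *undecimated* so sub-bands stay voxel-aligned with the
  mask, with periodic boundary handling. The two-letter sub-band labels
  imply a 2D decomposition; voxel alignment is what lets the same 3D ROI
  be reused on every sub-band. The orthonormal decimated transform serves
  as the oracle in the test suite (the undecimated coefficients coincide
  with the decimated ones at odd in-plane positions).
* **Degenerate ROIs**: a constant ROI is flagged; its histogram entropy is
  0 and energy 1, GLCM correlation is defined as 1, skewness/kurtosis as 0,
  so the vector length never varies.
* **Cropping**: after whole-volume normalization, computation proceeds on
  the mask bounding box plus a 2-voxel margin. All features only read
  in-mask voxels and the Haar filters reach one voxel, so the margin
  supplies the true neighborhood; this is purely a performance measure.

## Selection and modeling conventions

* **ICC model**: ICC(2,1) — two-way random effects, absolute agreement,
  single measurement — the standard choice when two specific radiologists
  are treated as a random sample of raters. Features with ICC < 0.8
  (threshold configurable) are dropped; zero-variance features are flagged
  degenerate and dropped.
* **Redundancy rule**: among each pair with |Pearson r| > 0.6 the feature
  with the lower ICC is dropped. The elimination order (ICC-descending,
  names breaking ties) makes the rule deterministic; the retained set
  provably satisfies max pairwise |r| ≤ 0.6. The absolute value is used
  because redundancy is sign-agnostic.
* **LASSO**: features are z-scored with training means/SDs stored in the
  signature; the penalty is chosen by stratified cross-validated binomial
  deviance with the 1-SE rule, which favors the very sparse signatures
  (1–4 features) this analysis aims for. A signature whose coefficients
  are all shrunk to zero is kept as an explicitly *empty* signature whose
  score is the intercept — this preserves the nine-column signature matrix
  and is itself informative (that habitat carries no reproducible signal).
* **Grid search**: candidate variable sets are all signature subsets of
  size 1–4 (the cap bounds the search while containing a three-signature
  optimum), each optionally augmented with the clinical block
  (all-or-nothing — per-covariate subsets would explode the grid). Cells
  are scored by mean accuracy at probability threshold 0.5 over R repeats
  of stratified 3-fold CV; ties break toward fewer variables, then the
  simpler family (LR < SVM < RF), then lexicographic names, so reruns are
  identical. The default grid (`model_grid_config()`) uses R = 10 repeats
  and small standard hyperparameter grids; `model_grid_config_light()`
  (R = 2, minimal grids) is the problem size used by the package's test
  suite and acceptance script — the search structure is identical, only
  the grid density differs.
* **SVM scoring detail**: during CV the SVM is scored by its native class
  prediction (decision value 0), which is the 0.5-probability decision;
  the Platt probability model is fitted only for the final model.

## The synthetic cohort

Patient data of this kind are private, so the generator is a first-class
module. It emulates: nine co-registered sequences at 0.7 × 0.7 × 4 mm
(4 mm slice thickness), a single ellipsoidal habitat per sequence spanning
at least 4 axial slices, responder prevalence 71/120, six clinical
covariates drawn from published cohort summaries (age ≈ 52 ± 9 y,
pregnancies ≈ 3 ± 1.6, rare positive family history) with *no* group
effect, and a second-radiologist re-segmentation modeled as random
boundary flips constrained to Dice ≥ 0.8.

The planted group difference lives in the *texture*, not the geometry:
inside the mask the signal is a Gaussian random field whose in-plane
correlation length and amplitude are patient-specific draws; in the
effect habitats (default `sag_T2`, `ax_T1c`, `adc` — mirroring the
habitats a real analysis selected) their means shift by `effect_size`
standardized units between groups (default 1.5, chosen a priori to give
single-habitat AUCs near 0.8 and test AUCs near 0.8–0.95 at n = 120).
Tumor size distributions are identical between groups, so shape features
are uninformative by construction; detection must come through the GLCM,
GLRLM, and histogram families. What the generator does **not** emulate:
MR physics (bias fields, coil profiles, sequence-specific contrast),
inter-sequence misregistration, multi-focal disease, or correlated
clinical covariates. Passing tests therefore demonstrate that the
*pipeline* recovers texture-borne group structure and stays honest on
null data — not that it would reach any particular performance on real
patients.

## Problem sizes and seeds

Every stochastic step consumes a named child seed derived from one master
seed, so a report is a pure function of (cohort config, pipeline config).
The test suite and acceptance script run the generator at reduced volume
shapes (between 20 × 20 × 10 and 32 × 32 × 16 voxels instead of the
64 × 64 × 32 default) with the study's cohort sizes (n = 120 with a 60/60 split for
effect recovery; n = 200 for null calibration; 20 repeated splits), which
keeps the full battery desk-scale. Volume shape is not part of the
statistical design, and effect recovery was verified at the reduced shape.
Only a fixed 25-patient subset of the training split is re-segmented (as
in a real reproducibility sub-study); repeated splits reuse the overlap of
their training half with that subset.

## Statistical conventions and edge cases

* AUC is the tie-corrected Mann–Whitney statistic; 95% CIs are
  AUC ± 1.96·SE with the DeLong variance, truncated to [0, 1].
* The Youden cutoff is chosen on training scores only; ties break toward
  the lower threshold (with a 1e-9 guard against floating-point noise in
  the rational sensitivity/specificity sums); `score >= cutoff` classifies
  as responder.
* Hosmer–Lemeshow uses equal-count risk bins (ties unsplit), merging bins
  with degenerate expected counts, and reports p from χ² with g − 2
  degrees of freedom — the convention for model-derived probabilities.
  (With *known* probabilities the statistic is χ² with g degrees of
  freedom; the test suite checks the null distribution of the statistic
  accordingly.) Constant score vectors yield a flagged NA rather than an
  error, since a degenerate model must not crash a null-cohort run.
* Univariate clinical tests: t-test when both groups pass Shapiro–Wilk at
  α = 0.05, otherwise Mann–Whitney; χ² unless an expected cell is < 5,
  then Fisher's exact (which is conservative — its realized type-I rate
  on rare binary covariates sits well below 5%).
* The multivariable logistic fit flags (quasi-)separation and suppresses
  Wald p-values in that case.
* Learner edge cases found the hard way: `randomForest` does not terminate
  on an all-constant design (which a subset of empty signatures produces),
  so constant columns are dropped and a prevalence stub is used when
  nothing varies; the scale-based SVM kernel width guards zero variance.

## Known limitations

* The 114-descriptor inventory reproduces the stated families, counts and
  naming scheme, but the per-family composition of the original private
  toolbox is not observable; where a published signature names a feature
  (e.g. `XLL_GLRLM_SRLGLE`), that feature exists here with the standard
  definition.
* Shape features are computed once per habitat mask; with per-sequence
  masks that differ only by delineation noise this is the natural reading.
* The generator's effect mechanism is in-plane; through-plane texture is
  dominated by the 4 mm slice spacing, as in the imaging protocol.
* Exclusion rule "more than 3 slices of tumor" is ambiguous in direction;
  the QC filter exposes both a minimum and maximum slice bound and the
  generator guarantees ≥ 4 slices, so the rule is configurable rather than
  guessed.
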