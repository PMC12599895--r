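---
title: "Temporal-subtraction CAD for sequential mammograms: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal-subtraction CAD for sequential mammograms: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Screening mammography compares a woman's current exam against her history.
A mass that is absent from the prior round and present in the recent one is
the single most actionable finding, yet it is also the easiest to miss in
dense breasts, where fibroglandular tissue hides lesions. Temporal
subtraction automates the comparison: the prior view is deformably
registered onto the recent one and subtracted, so anatomy that did not
change cancels and newly developed or denser tissue stays bright. Candidate
regions segmented from the residual are then described numerically and
classified in two rounds — candidate vs. normal tissue first, then benign
vs. malignant — under patient-wise cross-validation.

`subtracad` implements that pipeline end to end, together with a seeded
phantom generator that emulates a two-round screening cohort, so every stage
is testable without clinical images.

```{r, eval = FALSE}
library(subtracad)
cfg <- cohort_config(n_patients = 1, image_shape = c(128, 104), seed = 1)
pat <- generate_patient(cfg, "P001", patient_class = "malignant")
pp_r <- preprocess_pipeline(pat$images$CC_recent)
pp_p <- preprocess_pipeline(pat$images$CC_prior)
reg <- demons_register(pp_r$image, pp_p$image)
res <- temporal_subtract(pp_r$image, reg$warped, pp_r$mask)
rois <- detect_candidates(res, pp_r$mask)
features <- extract_all(rois[[1]], res)
```

## The phantom cohort

The generator's defaults encode the structure of the cohort the method is
designed for: 100 patients, two views (CC, MLO), two screening rounds (400
images), BI-RADS density classes a–d in proportions 11/45/39/5 per 100
patients, and a 35/15/50 normal/benign/malignant patient mix. Per view, a
prior image of normal anatomy is generated first; the recent image is the
prior warped through a stored smooth random deformation field (positioning
and compression differences), with masses inserted for mass patients, a
low-frequency multiplicative intensity drift, and additive Gaussian noise.

Modeling choices, each the simplest mechanism that reproduces the
clinically relevant behavior:

* **Breast region**: a half-ellipse anchored on the chest wall (left image
  edge), with jittered semi-axes. Fibroglandular texture is band-pass
  filtered Gaussian noise whose amplitude grows with density class
  (0.03/0.06/0.10/0.14 on the unit intensity scale for a–d), reproducing
  the density-dependent visibility problem.
* **Masses**: a radial boundary $r(\theta) = R\,(1 + \sum_k a_k
  \cos(k\theta + \phi_k))$. Benign masses use low-order harmonics
  ($k \in \{2,3\}$, $a_k \le 0.08$) and are near-circular with smooth
  margins; malignant masses use four high-order harmonics
  ($k \in 7..13$, $a_k$ up to 0.3), giving spiculated, irregular outlines.
  Shape features are therefore discriminative by construction. The
  intensity bump adds `mass_contrast` (default 0.25) at the core, at least
  half that at the margin.
* **Deformation**: a sum of three random Gaussian bumps rescaled so the
  maximum displacement equals `deformation_magnitude` (default 4 px).
  Because the recent image is defined as the prior warped through this
  field, the stored field is exactly the backward field a registration of
  prior onto recent should recover, which makes registration-recovery
  error measurable.
* **Mass placement** keeps centers clear of the skin line
  (`1.6 R + min(dim)/10` pixels inside the breast). Peripheral candidates
  are discarded by the detection stage by design, so cohort masses must
  lie in the breast interior — matching a screening population, where
  masses at the skin line are rare.
* **Drift**: the multiplicative inter-round intensity drift amplitude is
  tied to `noise_sigma` rather than being a separate knob, so a noise-free
  configuration is exactly reproducible between rounds.
* Images are quantized to the 16-bit storage grid before being returned,
  so in-memory pixels equal what `generate_cohort()` writes to disk and
  cohorts are bit-reproducible from `(config, seed)`.

What the phantom does **not** model: X-ray physics (scatter, beam
hardening), vendor post-processing, pectoral muscle, calcifications, and
real lesion texture. Passing tests on phantoms therefore demonstrate that
the pipeline's machinery is correct and self-consistent — not that its
clinical performance on real mammograms matches any reported figure.

## Pre-processing

Stages run in the fixed order CLAHE → gamma correction → border removal,
on an internal [0, 1] float scale (conversion back to the source bit depth
happens only on write).

* **CLAHE** (`apply_clahe`): contrast-limited adaptive histogram
  equalization via EBImage, 8×8 tiles, normalized clip limit 0.01. The
  exact values used in the original study are not public; both are exposed
  in the configuration.
* **Gamma** (`gamma_correct`): $x^\gamma$, default 1.2 — a mild darkening
  that counteracts CLAHE's brightening of the background; rank order of
  intensities is preserved, and the map is a bijection on (0, 1].
* **Border removal** (`remove_border`): Otsu threshold computed on a
  Gaussian-blurred copy (σ = 3 px; blurring suppresses the background
  noise CLAHE amplifies), morphological opening (disc r = 5), removal of
  components touching two or more image edges (frame lines, labels),
  largest remaining component, then a closing and hole fill. The closing
  smooths boundary notches which would otherwise poison the erosion used
  by peripheral-candidate removal downstream. On phantoms the recovered
  mask overlaps the true breast region with Dice ≥ 0.95.

## Registration

`demons_register` implements the classic intensity-driven Demons scheme:
at each iteration the displacement update at every pixel is

$$u = \frac{(f - m \circ s)\,\nabla f}{\|\nabla f\|^2 + (f - m \circ s)^2},$$

capped at 2 px per axis, after which the accumulated field is smoothed
with a Gaussian (σ = 2 px), inside a 3-level coarse-to-fine pyramid with
15/30/60 iterations from fine to coarse. The schedule was chosen as the
smallest one whose endpoint-error recovery plateaued on phantom pairs;
everything is configurable. Two guarantees are built in: the identity
field is returned whenever optimization fails to reduce the mean squared
difference (registration never makes a pair worse), and on identical pairs
the field is exactly zero.

`affine_register` provides the global 6-parameter baseline (Nelder-Mead on
lightly blurred images, never worse than identity). On phantom pairs with
known elastic deformations, Demons recovers the applied field with a mean
endpoint error below 30 % of the mean applied displacement and always
reaches a residual MSE at or below the affine baseline's — the qualitative
comparison the method is motivated by.

## Subtraction and its metrics

`temporal_subtract` computes `max(recent − warped prior, 0)` inside the
breast mask. Negative differences are clipped: new or denser tissue is
bright in the recent image, while structure that vanished between rounds
is out of scope (in screening practice a stable-to-shrinking mass is
followed up, not biopsied, so the clipped direction carries the clinical
signal).

Two conspicuity metrics quantify what subtraction buys:

* `contrast_ratio`: mean intensity over the lesion mask divided by mean
  intensity over a background mask. The definition (and the choice of
  background = breast interior minus the dilated lesion masks) is a package
  convention, documented because the quantity is often reported without
  one.
* `background_reduction`: $100\,(1 - \mu_{after}/\mu_{before})$ over the
  background mask.

On default phantoms both move the way a working subtraction should:
background mean drops by roughly 90 % and the contrast ratio gains a
factor of 4–5 (the exact values are recomputed by
`scripts/acceptance.R`).

## Candidate detection

Three steps, each idempotent on its own output:

1. **Thresholding** at the 95th percentile of the nonzero residual inside
   the breast — percentile-based, hence robust to global intensity shifts.
   Lower values admit more false positives; higher values risk fragmenting
   weak masses. The default leaves false-positive control to the round-1
   classifier, which is the design intent of the whole pipeline.
2. **Morphological cleaning**: closing then opening with a disc (radius
   `min(dim)/80`), hole filling, removal of components below 0.13 % of the
   frame area. Closing runs first because the thresholded footprint of a
   spiculated mass is often fragmented; consolidating it before the
   opening preserves the mass while the opening still removes isolated
   specks.
3. **Peripheral removal**: components whose centroid lies within
   `min(dim)/13` pixels of the breast boundary (erosion test) are
   discarded — skin-line registration artifacts concentrate there.

The spatial parameters scale with image size and reproduce the package's
reference values (radius 2, min area 40 px, margin 12 px) at the default
192×160 phantom resolution. Detected components become `candidate_roi`
objects (8-connected, area-sorted, 0-based half-open bounding boxes);
`match_to_truth` tallies them against ground truth at a lenient IoU of
0.1, because the quantity of interest is per-mass detection, not
segmentation quality. On default 50-patient cohorts, 100 % of inserted
masses survive the three steps — the testable analog of the requirement
that segmentation must not lose a single true mass.

## The 98-feature vector

`extract_all` produces a frozen, ordered catalog of 98 values per ROI:

* **72 GLCM** values: four Haralick statistics (correlation, contrast,
  energy, homogeneity) × three distances (D1 = 1, D2 = 2, D3 = 4 px) ×
  six angle slots (0°, 45°, 90°, 135°, plus the mean and SD over the four
  directions). Pixels are quantized to 16 gray levels over the ROI
  min–max; matrices are symmetric and normalized. A constant ROI follows
  the degenerate conventions correlation 0, contrast 0, energy 1,
  homogeneity 1.
* **10 first-order statistics**: mean, SD, variance, skewness, excess
  kurtosis, Shannon entropy (bits, 64-bin histogram), histogram energy,
  median, 1st and 99th percentiles.
* **4 intensity** features: maximum, mean, minimum, range.
* **12 shape** features: area, perimeter, major/minor axis of the
  second-moment ellipse, eccentricity, orientation, equivalent diameter,
  extent, convex area, filled area, solidity, circularity $4\pi A/P^2$.
  The perimeter is the oriented-contour chain length with the standard
  0.95 digitization correction, so a digital disk of radius 20 measures a
  circularity near 1; the convex area is exact for the union of pixel
  squares (hull of all pixel corners).

The catalog is the minimal consistent reconstruction containing every
feature the study names in its selected-feature lists; sizes 16 levels and
distances 1/2/4 are common radiomics defaults, exposed in `glcm_spec()`.
`resolve_feature_name()` maps report-style names ("Correlation 90 D2",
"Maximum intensity", "Filled Area", …) onto catalog identifiers, and both
published per-round selection lists resolve completely. Shape features are
computed in pixels; physical units are optional via `pixel_spacing`
because whether the study measured in mm is not public.

## Consensus feature selection

Eight filter methods spanning univariate and multivariate criteria rank
all features: Welch t score, Wilcoxon rank-sum score, mutual information
and chi-square on quantile-binned features (5 bins; discrete features keep
one bin per value), Fisher score, ReliefF (k = 10), greedy mRMR, and
random-forest Gini importance. Ties break by catalog order, so rankings
are deterministic given data and seed. `majority_select` keeps features
present in the top-K of at least 5 of the 8 rankings;
`tune_consensus_k` scans K so the consensus size matches a target (19
features for round 1 and 17 for round 2, the sizes the method reports).
With 5 informative features planted among 98 at one SD of class
separation and 200 ROIs, the consensus recovers on average all 5 over 20
seeds.

Selection runs inside each cross-validation training fold only; a
dedicated test verifies that changing a held-out patient's labels never
changes that fold's selection.

## Classifiers and evaluation

`classifier_spec` wires the suite with round-specific defaults: LDA (equal
priors), kNN with k = 11 (round 1) / k = 5 (round 2) and a
nearest-neighbor tie-break, RBF-kernel SVM, random forest (300 trees),
MLP, AdaBoost (50 stumps), bagged trees (25), gradient boosting (100
rounds, depth 3, η = 0.1), a soft-voting ensemble (round 1: kNN, SVM,
MLP, AdaBoost, GB; round 2: LDA, RF, GB) whose score is the mean of
member probabilities, and the ANN. Hyperparameters the study does not
state are fixed, seeded defaults, all overridable through `params` — the
original values were tuned iteratively and are not public.

The ANN (`build_ann`) is a compact feed-forward network written in base R
matrix operations: five hidden layers in round 1, one in round 2; ReLU
activations and a softmax output; Adam with batch size 128, learning rate
1e-4, up to 100 epochs; input Gaussian noise, affine-free batch
normalization and dropout for regularization; early stopping on a held-out
validation split with best-weight restoration. In round 2 features are
deliberately not standardized. All randomness derives from the spec seed,
so two fits are bit-identical.

`smote_balance` equalizes training-fold class counts by interpolating
between minority neighbors; a geometric test asserts each synthetic point
lies on a segment between two minority samples. SMOTE, standardization,
selection and fitting are all re-done inside each training fold of
`lopo_cv` (one fold per patient) and `kfold_cv` (folds partition patients,
sizes differing by at most one; k = number of patients reproduces LOPO).
Single-class training folds are skipped with a warning rather than
fabricating a fit.

`compute_metrics` reports the confusion counts, sensitivity, specificity
and accuracy in percent, rank-based (trapezoidal) AUC, Matthews
correlation and Cohen's kappa, with seeded bootstrap percentile 95 % CIs
(2000 resamples by default; the CI method is a package choice since the
original is unstated). `mcnemar_compare` uses the exact two-sided binomial
for discordant totals up to 25 and the continuity-corrected chi-square
above; `mcnemar_all_pairs` extends the comparison across a classifier set
with Holm correction — our reading of an "extended" McNemar procedure.

One worked example anchors the metric code to published numbers: the
misclassification counts 90 benign with 4 false malignant calls and 103
malignant with 6 false benign calls give TP = 97, FN = 6, TN = 86, FP = 4,
hence sensitivity 94.17 %, specificity 95.56 %, accuracy 94.82 % and
MCC 0.896, reproduced exactly at printed precision. The kappa implied by
these counts is ≈ 0.896; the independently printed value 0.865 is not
consistent with them, so the package does not target it.

## Numerical choices and degenerate inputs

* Internal scale [0, 1]; no NaN/Inf ever leaves a public function —
  undefined metric denominators return `NA` explicitly.
* Seeds: one user-facing seed is fanned out per stage and per patient via
  `derive_seed` (a deterministic hash kept below 2³¹), so any stage can be
  re-run in isolation and generators never disturb the caller's RNG
  stream.
* Zero-variance ROI: GLCM correlation defined as 0; entropy 0; energy 1.
* All-zero residual: empty candidate mask, not an error. Empty
  foreground at border removal and mass-placement failure after bounded
  retries are errors, with the cause in the message.
* Ties: kNN votes break by the single nearest neighbor; rankings break by
  catalog order; `majority_select` is a set operation, invariant to
  ranking order.

## Problem sizes used by the tests

The test suite and `scripts/acceptance.R` run phantoms at 128×104 px (the
package's test-scale resolution) with cohort structure unchanged, and the
mass-retention check uses the default 50-patient cohort at 192×160.
Registration recovery uses 10 pairs, selection recovery 20 seeds, metric
oracles 10⁴ random prediction vectors. These sizes are the package's
reference experiment; the statistical behavior they probe (recovery
ratios, retention, consensus recovery) was verified to be stable across
seeds at these sizes.

## Known limitations

* The phantom is a geometric emulation; no claim of radiographic realism.
* Demons here is the classic first-order variant — no diffeomorphic
  guarantee; strong compression differences beyond the configured
  magnitude are out of its capture range.
* The clipped subtraction cannot flag disappearing structure.
* The 98-feature catalog is a reconstruction constrained by the published
  selected-feature lists, not a copy of the study's (non-public) list.
* Published cohort-level accuracies are properties of a private clinical
  dataset and are not reproduction targets; the package's tests assert
  directions, contracts and recoveries that are provable on synthetic
  data.
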