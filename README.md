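# subtracad

Computer-aided detection and classification of breast masses from
**temporally sequential mammograms**.

Mammographic screening produces pairs of exams per patient: a prior round
and a recent one. A newly developed mass is the most actionable finding and
the easiest to miss, especially in dense breasts. `subtracad` automates the
comparison radiologists do by eye: it registers the prior view onto the
recent one with a deformable (Demons) registration, subtracts, and works on
what remains — anatomy that did not change cancels out, new or denser
tissue stays bright.

The pipeline, per patient and view:

1. **Pre-process** both rounds: CLAHE, gamma correction, breast border
   removal.
2. **Register** the prior onto the recent view with the Demons algorithm
   (an affine baseline is included for comparison); the estimated
   displacement field `s` minimizes the intensity mismatch under iterative
   updates `u = (f − m∘s)∇f / (‖∇f‖² + (f − m∘s)²)` with Gaussian field
   smoothing in a coarse-to-fine pyramid.
3. **Subtract**: residual `max(recent − warped prior, 0)` inside the
   breast mask.
4. **Detect** candidate masses from the residual: percentile thresholding,
   morphological cleaning, peripheral removal.
5. **Describe** each candidate with a frozen 98-value feature vector:
   72 gray-level co-occurrence (Haralick) statistics (correlation,
   contrast, energy, homogeneity × distances D1/D2/D3 × angles
   0°/45°/90°/135° plus mean/SD aggregates), 10 first-order statistics, 4
   intensity features, 12 shape features (area, perimeter, circularity
   4πA/P², solidity, ...).
6. **Select** features by majority rule over 8 ranking methods (t score,
   Wilcoxon, mutual information, chi-square, Fisher score, ReliefF, mRMR,
   random-forest importance): a feature is kept when ≥ 5 of 8 rankers place
   it in their top-K.
7. **Classify** in two rounds — candidates vs. normal tissue, then benign
   vs. malignant — with a suite of classifiers (LDA, kNN, SVM, RF, MLP,
   AdaBoost, bagging, gradient boosting, a soft-voting ensemble, and a
   multi-layer ANN trained with Adam, dropout, batch normalization and
   early stopping), SMOTE balancing inside training folds, and
   **leave-one-patient-out** or patient-grouped k-fold cross-validation.
   Reports include sensitivity, specificity, accuracy, AUC, Matthews
   correlation, Cohen's kappa, bootstrap CIs, and McNemar comparisons
   between classifiers.

Because clinical two-round datasets with biopsy-confirmed annotations are
not publicly available, the package ships a **seeded phantom generator**
(`cohort_config`, `generate_patient`, `generate_cohort`) that emulates the
cohort structure such a study uses — 100 patients × 2 views × 2 rounds,
BI-RADS density classes a–d at 11/45/39/5 per 100, 35/15/50
normal/benign/malignant mix, smooth inter-round deformations with stored
ground truth, and round/smooth (benign) vs. spiculated/irregular
(malignant) masses — so every stage is testable offline.

## Worked example

```r
library(subtracad)

cfg <- cohort_config(n_patients = 1, image_shape = c(128, 104), seed = 1)
pat <- generate_patient(cfg, "P001", patient_class = "malignant")

pp_r <- preprocess_pipeline(pat$images$CC_recent)
pp_p <- preprocess_pipeline(pat$images$CC_prior)
reg  <- demons_register(pp_r$image, pp_p$image)
res  <- temporal_subtract(pp_r$image, reg$warped, pp_r$mask)
rois <- detect_candidates(res, pp_r$mask)
mt   <- match_to_truth(rois, pat$truth$views$CC$mass_masks,
                       pat$truth$views$CC$mass_labels)
```

Summarizing the run (with `contrast_ratio` and `background_reduction`
computed against the breast interior minus the dilated lesion masks)
prints:

```
candidates: 1 | true masses: 1 | detected: 1 | FPs: 0
background reduction: 91.2% | contrast ratio: 1.57 -> 6.69
```

The inserted malignant mass is the single candidate; subtraction removed
91 % of the background intensity and raised the lesion-to-background
contrast ratio from 1.57 to 6.69 — the conspicuity gain the method is
built for. Its feature vector (5 of the 98 entries):

```r
round(extract_all(mt$rois[[1]], res)[c("GLCM_Correlation_Mean_D1",
      "FOS_STD", "Intensity_Maximum", "Shape_Circularity",
      "Shape_Solidity")], 3)
#> GLCM_Correlation_Mean_D1                  FOS_STD        Intensity_Maximum
#>                    0.576                    0.070                    0.304
#>        Shape_Circularity           Shape_Solidity
#>                    0.985                    0.908
```

The low circularity/solidity combination typical of spiculated masses is
what the round-2 classifier exploits. The evaluation side is anchored by a
worked confusion-matrix example (90 benign masses with 4 false malignant
calls, 103 malignant with 6 false benign calls):

```r
m <- metrics_from_confusion(tp = 97, fn = 6, tn = 86, fp = 4)
#> sensitivity 94.17% | specificity 95.56% | accuracy 94.82% | MCC 0.896
```

A command-line front-end over the same functions is installed at
`inst/cli/subtracad.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/subtracad.R", package="subtracad"))')" \
    run --out runs/demo --seed 1 --patients 10
```

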