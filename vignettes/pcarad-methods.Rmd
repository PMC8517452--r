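---
title: "Methods: radiomics characterization of prostate cancer aggressiveness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: radiomics characterization of prostate cancer aggressiveness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the pipeline

Multiparametric prostate MRI (mpMRI) combines T2-weighted anatomy, the
apparent diffusion coefficient (ADC) map from diffusion imaging, and dynamic
contrast-enhanced (DCE) uptake. Low ADC marks dense, cellular tissue; the
inverse relation between ADC and Gleason grade is one of the most robust
quantitative findings in prostate imaging. `pcarad` implements a fully
automatic chain that turns four co-registered 3D channels plus a lesion mask
into a calibrated *radiomics score* for the probability that a lesion is
highly aggressive (Gleason grade group > 2, i.e. GS >= 4+3), and bands that
score into three clinical levels (indolent / indeterminate / aggressive).

The stages, each an exported function:

1. **Candidate detection** (`filter_voxels`, `extract_candidates`,
   `select_lesion`): a voxel survives iff malignancy probability >= 0.60,
   ADC within 200–1600 (units 1e-6 mm²/s) and first-minute uptake >= 100%.
   26-connected components whose maximal axial cross-section strictly
   exceeds 100 mm² become candidates; the candidate best overlapping a
   confirmed mask (Dice) stands in for the radiologist's selection.
2. **Preprocessing** (`denoise_gaussian`, `resample_isotropic`,
   `resegment_roi`, `discretize_fbn`): Gaussian de-noising (sigma 0.5 mm),
   isotropic 0.5 mm resampling (trilinear images / nearest-neighbour masks),
   1st–99th percentile ROI re-segmentation, fixed-bin-number (FBN)
   discretization.
3. **Feature extraction** (`extract_feature_vector`): the 92-feature vector —
   ROI volume; 8 ADC intensity statistics; the ADC intensity-histogram mean;
   25 grey-level co-occurrence (GLCM) and 16 run-length (GLRLM) features per
   channel (ADC and T2w), each computed in the 13 unique directions of a 3D
   grid and averaged. T2w contributes texture only: its intensities are not
   quantitative across scanners.
4. **Feature selection and training** (`agg_fit`): min–max normalization;
   per-feature bootstrap AUC ranking; pruning of feature pairs with
   |Pearson rho| > 0.9 (the lower-AUC member is dropped); an AUC-ranked
   wrapper scanning nested subsets with a third-order polynomial-kernel SVM
   under stratified, patient-grouped 4-fold cross-validation; a box-constraint
   grid search over C = 1..50; final SVM training with Platt-style score
   calibration; Youden-index and NPV-maximizing cutoffs on the training
   scores.
5. **Banding** (`assign_agg_score`): aggressive iff score > Youden cutoff;
   indeterminate in the band from 85% of the cutoff up to the cutoff;
   indolent below.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `sigma_mm` | 0.5 | mm | de-noising width; 0 disables |
| `iso_spacing_mm` | 0.5 | mm | isotropic grid for rotation-invariant texture |
| `reseg_lo_pct`, `reseg_hi_pct` | 1, 99 | percentile | outlier removal inside the ROI |
| `n_bins_intensity` | 64 | — | FBN bins for intensity-histogram statistics |
| `n_bins_texture` | 32 | — | FBN bins for GLCM/GLRLM |
| `prob_min` | 0.60 | probability | voxel keep threshold |
| `adc_min`, `adc_max` | 200, 1600 | 1e-6 mm²/s | plausible-tumour ADC band |
| `uptake_min` | 100 | % | minimal first-minute enhancement |
| `min_area_mm2` | 100 | mm² | candidate gate (maximal axial area, strict) |
| `rho_max` | 0.9 | — | correlation-pruning threshold (strict) |
| `k_folds` | 4 | — | CV folds for wrapper and grid search |
| `C_grid` | 1..50 | — | box-constraint grid |
| `band_fraction` | 0.15 | — | indeterminate band below the Youden cutoff |

Two bin counts coexist deliberately: the 64-bin discretization feeds the
intensity-histogram statistics, while an independent 32-bin discretization
feeds the texture matrices. That is the only reading under which both
settings can hold simultaneously, and it keeps histogram resolution high
where values are quantitative (ADC) while keeping texture matrices dense.

The ADC thresholds are stored with explicit units. Raw mm²/s at these
magnitudes would be physically implausible for tissue water diffusion; the
band 200–1600 × 1e-6 mm²/s is the standard prostate range, with normal
peripheral zone above it and only dense tumour inside it.

## Numerical conventions

* **Percentiles** use linear interpolation between order statistics
  (R's type-7 default): for a 100-voxel ROI valued 1..100, P1 = 1.99 and
  P99 = 99.01, so re-segmentation at 1–99% removes exactly the extreme two
  voxels.
* **FBN discretization**:
  `level = min(n_bins, 1 + floor(n_bins (x - min)/(max - min)))`; a constant
  ROI maps to level 1. FBN is invariant to positive affine intensity
  rescaling, which is the point of using it on non-quantitative T2w.
* **Gaussian filtering** uses a sampled, normalized kernel truncated at
  4 sigma with reflective boundaries; reflection avoids edge darkening on
  the small cropped fields the extractor works in.
* **Resampling** aligns the output grid to the input origin with
  `round(n * spacing / target)` voxels per axis, preserving extent to within
  one voxel; trilinear interpolation reproduces affine intensity ramps
  exactly, and a single-voxel axis falls back to nearest neighbour.
* **GLCM** matrices are symmetrized and normalized per direction; directions
  with no valid voxel pair are excluded from the 13-direction average rather
  than contributing zeros. Degenerate conventions: with a single occupied
  grey level, correlation and both information-correlation features return 0.
* **GLRLM** runs are maximal in-mask runs; a masked-out voxel terminates a
  run. Run percentage divides by in-mask voxels (per direction), or by
  voxels × directions when matrices are merged.
* **Aggregation**: features are computed per direction and arithmetically
  averaged (the operational description), with merged-matrix aggregation
  available via `preprocess_config(merge_matrices = TRUE)`. The 13-direction
  average is exactly invariant under the 48 axis-aligned cube symmetries on
  isotropic grids, which the tests verify to 1e-8.
* **Kurtosis** is excess kurtosis (normal = 0) both for raw ADC values and
  for the intensity-histogram statistics computed on discretized levels;
  that distinction is what makes the eight ADC statistics non-redundant.
  Zero-variance ROIs define skewness and kurtosis as 0.
* **Cutoffs**: candidate thresholds are midpoints between adjacent sorted
  unique scores plus the two flanking values, with positives called strictly
  above the cutoff. Youden ties break toward higher specificity (the larger
  cutoff); NPV ties break by maximal specificity, then the lower threshold —
  many thresholds reach NPV = 1 on well-fitted training scores, and a single
  reported value needs a deterministic rule.
* **Overfitting point** for the wrapper: the smallest subset size whose mean
  CV test accuracy is maximal and is not exceeded at the next two sizes.
  The qualitative description — training accuracy keeps rising while test
  accuracy stops improving — has no unique formula; this rise-then-plateau
  rule is the package's operationalization.
* **Calibration**: the SVM decision value is orientation-corrected (so
  larger means more aggressive) and mapped through a logistic regression of
  the training labels on the decision value — a Platt-style monotone map to
  [0, 1], clamped. It is fully deterministic, which the bit-reproducibility
  guarantee requires; whether the original score was a calibrated
  probability or a rescaled decision value is not stated anywhere we could
  verify, so this choice is documented rather than attributed.
* **CV folds** are stratified by class and grouped by patient, so two
  lesions of one patient can never sit on opposite sides of a fold split;
  the fold cycle continues across classes so that even cohorts with as many
  patients as folds fill every fold.
* **Confidence intervals** on confusion proportions are Wilson score
  intervals; degenerate counts (0/n, n/n) pin the corresponding bound to 0
  or 1. Undefined predictive values (no positive or no negative calls) are
  reported as missing, never as 0.
* **Mann–Whitney** switches from exact enumeration (both samples <= 8) to
  the tie-corrected normal approximation; the DeLong comparison of paired
  AUCs delegates to pROC and returns p = 1 for zero-variance differences.

## The synthetic phantom: what it does and does not emulate

No imaging data ships with the package; every test substrate is generated by
`simulate_phantom()` / `simulate_feature_table()` under explicit seeds.

The phantom emulates the *statistical contract* the pipeline relies on:

* two lesion classes whose ADC means are ordered (high-aggressive 850 vs
  low-aggressive 1100 × 1e-6 mm²/s, both inside the detection band) —
  the ADC–grade inverse relation imposed as a generative assumption;
* class-dependent texture regularity through the correlation length of a
  Gaussian random field (2.5 mm smooth vs 1.2 mm heterogeneous), which gives
  GLCM/GLRLM features genuine class signal rather than pure noise;
* class-dependent volumes (0.5–1.2 vs 0.9–2.0 ml, nothing below the 0.5 ml
  clinical-significance floor), carved as perturbed ellipsoids thresholded
  to the exact drawn target volume;
* lesions extended in-plane and flattened through-plane at fixed volume
  (in-plane factor 1.25–1.6), the way prostate lesions present on
  thick-slice axial acquisitions. This matters: a perfect 0.5 ml sphere has
  a maximal axial cross-section of about 76 mm² and would fail the 100 mm²
  candidate gate, while the gate's own rationale (a volume equivalent of the
  smallest significant lesion) presumes in-plane-dominant geometry;
* consistent auxiliary channels: probability >= 0.8 and uptake >= 130%
  inside lesions, low-probability enhancing-gland background outside.

It deliberately does **not** emulate MR physics: no bias fields, no Rician
noise floor, no rectal-coil intensity gradients, no DCE pharmacokinetics, no
registration error between channels, and the background is a homogeneous
random field rather than zonal anatomy. Passing tests therefore demonstrate
that the algorithms implement their definitions and recover planted
structure under the stated statistical conditions — not that the trained
phantom model transfers to clinical images. On phantom cohorts the classes
are widely separated by construction, so end-to-end AUCs near 1 are a
sanity ceiling, not a clinical claim.

Feature tables for the selection stages are multivariate Gaussian with unit
variances: informative columns get a class mean shift in sd units
(`delta_mu`), and equicorrelated blocks (e.g. rho = 0.95) exercise the
pruning path.

## Problem sizes

The shipped tests and the acceptance script size their simulations for a
single CPU: phantom grids of 72×72×28 voxels at 0.6×0.6×1.2 mm (whole-case
extraction runs in about a second because preprocessing operates on the
mask's padded bounding box), cohorts of 12–32 cases, oracle suites of 200
random ROIs up to 6³ voxels with up to 4 grey levels, 10–25 wrapper
replicates at 200 lesions × 23 features, and bootstrap depths of 150–1000
replicates. All are the package's own choices of desk-scale study
conditions; every number the documentation cites is recomputed at run time
by the tests or by `scripts/acceptance.R`.

## Known limitations

* The candidate gate's "area" reading (maximal axial cross-section vs a
  volume measure) is genuinely ambiguous in the source material; both are
  implemented (`detection_config(area_mode=)`), axial is the default.
* Whether de-noising was originally applied to both channels or T2w only is
  unknown; the default filters both (`denoise_channels`).
* ROI volume is measured on the resampled mask before re-segmentation by
  default (`volume_after_reseg` switches it): re-segmentation removes
  intensity outliers, not anatomy.
* Re-segmentation is applied per channel (ADC mask from ADC percentiles,
  T2w mask from T2w percentiles), since a single shared mask cannot honour
  both channels' percentile bands at once.
* No nested cross-validation: the wrapper's chosen subset and the reported
  CV accuracies share data, so CV accuracy at the chosen size is an
  optimistic estimate. Held-out cohorts (as in the acceptance script) give
  the honest number.
* The 92 monoparametric Mann–Whitney tests carry no multiple-testing
  correction, mirroring the source procedure; interpret single-feature
  p-values accordingly.
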