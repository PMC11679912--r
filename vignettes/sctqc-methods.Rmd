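---
title: "Predicting synthetic-CT HU accuracy without ground truth: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting synthetic-CT HU accuracy without ground truth: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(sctqc)
```

## The problem

Synthetic CT (sCT) volumes — CT-like Hounsfield-unit images generated from
MR or cone-beam CT acquisitions — are increasingly used for radiotherapy
dose calculation in place of a real planning CT. Their conversion accuracy
is conventionally measured as the per-slice Mean Absolute Error against the
registered ground-truth CT,

$$\mathrm{MAE} = \frac{1}{n}\sum_{i=1}^{n} \lvert GT_i - sCT_i \rvert,$$

over the $n$ pixels of an axial slice. In clinical deployment no ground
truth exists, so the conversion error is unknowable by direct computation.
`sctqc` implements an independent quality-control predictor: a model that
receives only the sCT slice and predicts its MAE, producing a slice-constant
"predicted MAE volume" (pMAE) that a clinician can fuse with the sCT to see
which craniocaudal regions of the conversion are trustworthy.

## The cascade

Predicting a continuous MAE directly from an image is hard; the package
therefore splits the task in two, following a coarse-to-fine design:

1. **Interval classification.** A 4-way classifier assigns the slice to one
   of four MAE intervals (low, medium-low, medium-high, high). The interval
   boundaries are the quartiles of the training-label distribution, which
   balances the number of examples per class; the open-ended high interval
   is closed by a saturation bound applied to all labels.
2. **Routed regression.** Four interval-specific regressors are trained, one
   per class; at inference only the regressor selected by the classifier's
   arg-max runs. Each regressor's *training* interval is its classification
   bin relaxed by ±5 HU (clamped to `[0, saturation]`), so that a slice
   misclassified into a neighbouring bin still lands inside the routed
   regressor's competence and the error can be recovered. Regression targets
   are affinely mapped from the relaxed interval to `[0, 1]` during training
   and inverted (then clipped to `[0, saturation]`) at inference.

Five estimators are trained per pipeline; exactly two run per slice. The
classifier's epoch selection does not use the cross-entropy value but a
class-distance-weighted accuracy,
$1 - \sum_j |\hat c_j - c_j| / (N(K-1))$, because a one-class error is
recoverable by the relaxed regression ranges while a two- or three-class
error is not. Regressor epochs are selected on validation MSE.

With the published quartile boundaries (MR 0/47/54/68 with saturation 100,
CBCT 0/27/32/42 with 70, MIXED 0/32/44/56 with 90), `bin_scheme()` +
`derive_regression_ranges()` reproduce the corresponding regression
intervals exactly; `scripts/acceptance.R` recomputes three of those interval
endpoints as its reproducibility check.

### Boundary conventions

Classification bins are half-open `[b_k, b_{k+1})` with the last bin closed
at the saturation bound: a label sitting exactly on a quartile belongs to
the upper bin. Regression membership uses closed intervals, so a label on a
relaxed-range endpoint trains both neighbouring regressors. Classifier
probability ties break toward the lowest class index. These tie-breaks are
arbitrary but fixed and documented; none of them affects more than the
measure-zero boundary set.

## Estimators

The estimator engine is written in the package (base-R matrix algebra):
convolutional and dense layers, ReLU, 2×2 max pooling, global average
pooling, softmax cross-entropy and MSE losses, L1+L2 penalties on weights
(not biases), Adam, and mirror/translation augmentation. A finite-difference
gradient check in the test suite verifies backpropagation through every
layer type.

Two backbones are defined:

* **`tiny`** (default for desk-scale work, 32×32 inputs): a fixed
  two-channel stem — the windowed intensity and a local roughness channel
  (mean absolute difference to the 4-neighbourhood) — followed by three
  1×1-convolution blocks of 16 feature maps, global average pooling and a
  small dense head (~900 parameters). The design is deliberate rather than
  merely small: the slice MAE is itself a spatial mean of per-pixel
  deviations, so pooled pointwise statistics of the intensity distribution
  are the natural sufficient features, and the architecture is exactly
  translation invariant.
* **`vgg16`**: the classical 13-convolution + 3-dense configuration used at
  clinical scale (224×224 inputs). It is defined in the same engine and its
  layers are covered by the gradient check, but training it is far outside
  the package's CPU-scale test envelope; it exists so a user with real data
  and hardware can run the identical pipeline at full size.

Preprocessing windows slices to `[-1000, 2000]` HU (air through dental
metal) and maps them linearly to `[0, 1]`; resampling is bilinear on pixel
centres, which reduces to exact block averaging for integer factors.

### Training configuration

`train_config()` carries the clinical-scale recipe: learning rate `5e-5`,
L1 and L2 weights both `4e-4`, cross-entropy/MSE losses, 75/10/15
train/validation/test split, mirroring plus random translations (default ±8
px), batch 32. The optimizer is Adam. Two choices deserve explanation:

* **Patient-level splitting.** Splits (and k-fold assignment, default
  `k = 5`) are always at patient level. Adjacent axial slices of one patient
  are nearly identical; a slice-level split would leak anatomy between train
  and test and overstate accuracy.
* **Desk-scale recipe.** `desk_train_config()` (Adam `1e-3`, 250 epochs,
  translations ≤ 2 px) is what the phantom experiments and tests use. The
  tiny backbone has ~900 parameters and trains on a few hundred 32×32
  slices, a regime where the clinical learning rate is needlessly slow; 2 px
  on a 32-pixel field of view is about the same fraction as 8 px on a
  clinical grid. Augmentation translates the input only and keeps the scalar
  label: translations are small and slices are padded with air, which leaves
  the slice MAE essentially unchanged.

Every stochastic stage (phantom generation, splits, initialization,
shuffling, augmentation) takes an explicit seed; inference is deterministic.

## The phantom generator

Because no patient data ship with the package, a digital head phantom stands
in for the training and evaluation cohorts. It is labelled synthetic
throughout and emulates, at desk scale, the features the pipeline actually
exercises:

* **Anatomy** (`generate_gt()`): elliptical soft-tissue body (40 HU) with a
  bone rim (700 HU) on an air background (−1000 HU), tapering toward the
  cranial end, with randomized air cavities concentrated near the volume
  ends — the analogue of the nasal-cavity region where sCT conversion
  typically degrades. Default scale: 32×32×20 voxels per patient, 8–12
  patients, which trains the tiny cascade in minutes on one CPU. These sizes
  are the package's chosen desk-scale study conditions and are used
  unchanged by the tests.
* **Corruption with exact labels** (`corrupt_to_target_mae()`): per slice, a
  zero-centred corruption field is rescaled so `mean(|field|)` equals the
  requested target MAE — the achieved slice MAE equals the request to
  numerical precision (the tests assert 1e-6 HU). Where adding the field
  would leave the valid `[-1024, 3071]` HU range, the field's sign is
  flipped pixel-wise, which preserves `|field|` and hence the label.
  CBCT-like corruption mixes a short-correlation smooth field with streak
  and cupping components; MR-like corruption is a longer-range smooth bias
  field. The two styles have measurably different spatial autocorrelation,
  enabling the modality-transfer experiments in miniature.
* **Per-slice MAE sampler**: uniform on `[0, 100]` HU by default, spanning
  low to saturated conversion quality so all four classes are populated.

What the phantom does **not** emulate: real CBCT scatter or beam-hardening
physics, MR sequence contrast, dental-metal artifacts, registration error,
or the long-tailed MAE distributions of clinical cohorts. Passing tests
therefore demonstrate that the pipeline's machinery — labelling, binning,
routing, training, recovery of a known per-slice error signal — works end to
end; they do not certify clinical accuracy on real sCT data, whose error
textures are subtler.

## Evaluation

With retrospective ground truth, prediction quality is measured per slice by
the signed Prediction Deviation $PD = MAE_{GT} - MAE_{pred}$ and its
absolute value APD; both MAE values are saturated to the scheme's upper
bound first. Summaries report the 5th/25th/median/75th/95th percentiles
(linear interpolation). Pipelines are compared with the two-sided Wilcoxon
rank-sum test on per-slice APD (`stats::wilcox.test`: exact enumeration for
small untied samples, normal approximation with tie correction otherwise).
The study design names the rank-sum test although the records are naturally
paired per slice; the test is implemented as named, and APD is used as the
comparison variable since it is the accuracy measure being contrasted. The
evaluation matrix runs exactly four experiments — CBCT→CBCT, MR→MR,
MIXED→CBCT, MIXED→MR — and rejects combinations outside it.

## Numerical choices and degenerate inputs

* Quantiles and percentiles use `stats::quantile` type 7 (linear
  interpolation between order statistics); interior bin boundaries are
  rounded to integer HU, and a distribution whose rounded quartiles are not
  strictly increasing is rejected as degenerate.
* Labels are saturated **before** binning; the default saturation is the
  maximum observed label rounded up to the nearest 10 HU, and the published
  bounds (100/70/90 HU) are set explicitly when reproducing the printed
  schemes.
* The MAE is computed over all pixels of the slice by default (a body-mask
  option exists but is off); slices with under 2% body fraction (GT pixels
  above −500 HU) are excluded from corpora as anatomy-free.
* HU values are clamped to `[-1024, 3071]` with a warning before labelling,
  guarding against sentinel values.
* Volume pairing requires identical shapes and geometry agreement within
  1e-3 mm; class indices are 1-based (1 = low MAE).
* An empty axial extent yields an empty slice list; an all-air dataset is
  rejected as an empty corpus; a regression bin with fewer than
  `min_regression_samples` training slices aborts training naming the bin.

## Problem sizes used by the tests

The test suite trains structural-check cascades on 5 phantoms × 8 slices
(15–25 epochs) and one accuracy-check cascade on 8 phantoms × 20 slices with
`desk_train_config()`, evaluated on 3 held-out phantoms; on that held-out
set it requires median APD ≤ 10 HU (10% of the 0–100 HU label span) and
median PD within ±5 HU of zero — the desk-scale analogue of the clinical
finding that predictions carry a few HU of absolute deviation and no
systematic bias.

## Known limitations

* The phantom's corruption is constructed for exact label control, not for
  artifact realism; accuracy numbers on phantoms do not transfer to clinical
  data.
* The `vgg16` backbone, while fully defined, is untrained and unvalidated
  here.
* One scalar per axial slice is predicted; voxel-level error maps are out of
  scope.
* The saturation bound caps what the pipeline can report: a catastrophic
  conversion (MAE far above saturation) is flagged only as "high".
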