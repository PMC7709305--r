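---
title: "Methods: segmentation-improvement strategies at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segmentation-improvement strategies at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oarseg)
```

## The problem

Deep-learning delineation of organs-at-risk on planning CT works, but not
perfectly, and the interesting question is which *strategies around the
model* — more data, augmentation, cost functions, inference-time windowing,
ensembling — actually move the needle. The salivary glands (submandibular,
SMG; parotid, PG) are the paradigm case: low grey-scale contrast with the
surrounding soft tissue, large shape variation between patients, and a
clinical cost to poor contours in head-and-neck radiotherapy.

`oarseg` implements those strategies as a tested toolkit. Because clinical
CT cohorts with reference contours are rarely shareable, the package ships
a synthetic phantom generator with exact ground-truth masks, so every
strategy and the full cross-validated experimental protocol can be
exercised end to end on a single CPU. The phantoms are *not* a claim about
clinical performance; they are a controlled substrate on which the
machinery — and the direction of the strategy effects — can be verified.

## Preprocessing

Every case is a CT volume plus a binary organ mask and a binary body mask.
The standard input chain in front of the model is:

1. **ROI crop**: a fixed-shape subvolume (64 × 64 × 32 voxels for the SMG,
   96 × 64 × 64 for the PG) centred on the organ-mask centroid rounded to
   the nearest voxel. Rounding the centroid makes the crop deterministic
   and translation-equivariant, which the test suite asserts. Regions
   beyond the volume boundary are padded with the window's lower HU bound
   (air-like relative to the window); masks pad with zero.
2. **HU window**: voxel values are clipped into the organ window,
   (−75, 175) HU for SMG and (−190, 310) HU for PG, removing bone and air
   extremes and stretching soft-tissue contrast. Clipping is idempotent.
3. **Normalisation**: the affine map sending the window's lower bound to 0
   and its upper bound to 1, followed by subtraction of the volume mean, so
   inputs are centred around 0. The divisor is the *window width*, not the
   per-volume range: after clipping the two generically coincide, and the
   fixed bounds keep the map well defined for degenerate (e.g. constant)
   volumes. This was a genuinely open choice; the fixed-bounds variant was
   selected for determinism.

Left and right glands are pooled under a symmetry assumption:
`flip_lateral()` mirrors a case across the left–right axis (an exact
involution) and toggles the recorded laterality.

## Data augmentation

**Traditional** augmentation applies generic transforms: the left–right
flip, rotation about all three axes with Euler angles uniform on
[0°, 360°), and additive Gaussian HU noise with σ = 15. Each enabled
operation fires independently with probability 0.5 (re-drawn if none
fires, so an augmented copy is never the identity); "0.5 each" is the
package's choice where only "randomly applied" is specified, and an
in-plane-only rotation mode is a config switch.

**Domain-specific** augmentation stays within plausible CT anatomy and
always applies three operations in order:

* *Elastic deformation* (Simard-style): a per-voxel displacement field
  drawn uniformly from [−1, 1] per axis, smoothed with a Gaussian of width
  σ = 3.8 / 5.8 voxels (SMG/PG), scaled by α = 38 / 58, plus an affine
  jitter of the identity whose linear part receives uniform
  [−1, 1] · α_affine / (mean grid extent) entries with α_affine = 3.8 /
  5.8. The exact affine functional form is not fixed by the parameter
  names alone; the normalisation by grid extent was chosen so that the
  quoted α values produce sub-voxel to few-voxel boundary displacements on
  the organ scale. The same field warps image (trilinear) and masks
  (nearest-neighbour), so masks stay binary and the organ remains inside
  the body up to boundary rounding (asserted with a one-voxel dilation
  tolerance). On a ball phantom the relative organ-volume change over 20
  fixed seeds stayed within ±0.315 (dominated by the determinant of the
  affine jitter); 0.35 is frozen as the regression bound.
* *Body density shift*: one N(0, 100²) HU offset added to every voxel in
  the body mask.
* *Organ density shift*: one N(0, 30²) HU offset added to every organ
  voxel.

Density shifts are expressed in HU, so augmentation operates on raw
volumes and *precedes* windowing/normalisation; the pipeline order is
fixed as augment → preprocess. Augmented copies are drawn only from a
fold's training cases and inherit that fold, so no test case ever
influences its own fold's training. Rotation and elastic warps fill
image regions entering from outside the grid with the volume minimum
(air-like), since at augmentation time no window has been chosen yet.

## Cost functions and metrics

The Sørensen–Dice coefficient is `SDC = 2tp / (2tp + fp + fn)`; the soft
training version replaces counts with sums of predicted probabilities.
Down-weighting true positives, `SDC(w) = 2w·tp / (2w·tp + fp + fn)` with
w = 0.5 or 0.05, raises the relative weight of surface errors. The
combined cost adds a Hausdorff penalty normalised by the ROI diagonal x
(the maximum possible HD on the crop grid):

    cost = (1 − softSDC) + HD / (0.33 x)

The printed form of this cost mixes a maximised quantity (SDC) with a
minimised one; since the optimiser minimises, the package uses
`1 − softSDC` as the Dice contribution by default and exposes
`use_negative_sdc = TRUE` for the `−softSDC` variant — both descend where
the coefficient ascends. The HD term is computed on the 0.5-binarised
prediction and enters as a non-differentiable penalty: gradients flow only
through the Dice term. For the SMG crop, x = √(64² + 64² + 32²) = 96 and
the normaliser is 0.33 · 96 = 31.68; an empty binarised prediction gets
the maximal flagged term 1/0.33.

The evaluation Hausdorff distance is the symmetric max–min Euclidean
distance between foreground voxel centres, in voxel-index space by default
(physical mm via `spacing` is available but not the default). It is
verified exactly against a brute-force all-pairs oracle. Both-empty-mask
Dice is defined as 1.0 with a `both_empty` flag; the soft Dice uses no
smoothing epsilon by default (an epsilon option exists for
empty-reference batches).

`contour_complexity()` — mean over axial slices of contour length divided
by foreground area, lower = smoother — supports data-curation analyses.
Contour length uses sub-pixel marching-squares segments at iso-level 0.5
rather than pixel-edge counting, which would systematically overestimate
perimeters; on a digital disk of radius 20 the estimator is within ~5% of
the continuum value 2/r.

## Patient-specific HU windowing

`search_best_window()` sweeps a grid of windows (centres −100…400 HU step
10, widths 100…1000 HU step 50; 969 candidates, both endpoints inclusive),
re-preprocesses the case per window, runs the predictor, and keeps the
window with the highest Dice against the reference — first maximiser in
centre-major scan order on ties. Predictions are recomputed per window (no
caching), since the window changes the model input. The search *requires*
the reference mask, so it is an evaluation/research tool: in de-novo
contouring there is no reference to score against, and mapping scan
characteristics to a good window is out of scope here.

## Ensembling

Members differ only by random parameter initialisation (and training
stochasticity). Voting operates on 0.5-binarised member predictions — a
voxel enters the ensemble mask iff at least `cutoff` members predict it —
with cut-off 1 the union, cut-off N the intersection, and
`majority_cutoff(n) = floor(n/2) + 1` (6 of 11 at the standard ensemble
size) the default for combined pipelines. Probability-averaging is
available as an option but is not the default. `sweep_cutoffs()` reports
every cut-off next to the stand-alone baseline (mean ± SD over members).

## Training backend

The package ships its own compact 3D fully-convolutional encoder–decoder
(U-net-style: per level one 3×3×3 convolution + ReLU + dropout + 2× max
pooling; a bottleneck convolution; nearest-neighbour upsampling with skip
concatenation on the way back; a 1×1×1 convolution and voxel-wise
sigmoid). Convolutions are im2col-based with BLAS matrix products and a
hand-derived backward pass, verified against finite differences in the
test suite. Dropout (default rate 0.2 on all convolutional layers) is
train-time only; inference is deterministic.

Training uses Adam (default learning rate 10⁻³; the desk-scale preset uses
10⁻²) with mini-batches of preprocessed crops. A random 10% of the
training cases forms the validation set, which never contributes
gradients. Early stopping: the monitored quantity is the validation value
of the configured cost, sign-adjusted so higher is better; *improvement*
is the current value minus the running best, and training stops once
improvement stays below 0.001 for 4 consecutive epochs, restoring the
best-validation parameters. The rule is exposed as the pure function
`early_stop_epoch()` and unit-tested against hand-simulated traces.
Learning rate, batch size, dropout rate and architecture size are exposed
configuration, not constants.

## The phantom generator

`generate_phantom()` draws a case from a fixed family: an elliptical
soft-tissue body (mean 40 HU, texture SD 15), one gland-like organ placed
laterally (mean 55 HU, SD 10 — a deliberately low 15 HU contrast), a
bone-like posterior rod (700 HU), air background (−1000 HU), and additive
acquisition noise (SD 10 HU), at 1 × 1 × 2.5 mm spacing. Gland shape
varies through random semi-axes and a smooth direction-dependent radial
perturbation (three random cosine modes on the sphere), which produces the
irregular organ shapes that make ensembling and augmentation interesting.
Masks are exact by construction; generation is a pure function of
(config, seed, laterality), and cohorts balance lateralities to within
one case.

What the phantoms do **not** emulate: anatomical neighbourhood structure
(mandible, vessels, overlapping organs), metal artefacts, scanner-specific
noise texture, inter-observer contour noise, and multi-organ context.
Passing directional tests on phantoms therefore demonstrates that the
machinery behaves as designed and that the strategy effects point the
right way on a low-contrast segmentation task — not that clinical effect
sizes are reproduced.

## Problem sizes

Desk-scale conditions are fixed once in `desk_scale_config()` and used by
the tests, the acceptance script and the examples: phantom grid
48 × 48 × 24 voxels, gland semi-axes 4–6 / 4–6 / 2–3 voxels, ROI crop
16 × 16 × 8 with the SMG window, model depth 2 with 4 base filters,
Adam at 10⁻², batch 4, ≤ 10–12 epochs, cohorts of 12–24 cases with
six-fold cross-validation, 5-member ensembles (3 in the combined arm) and
a coarsened window grid (6 centres × 4 widths) inside the combined
pipeline. These sizes keep a full strategy comparison in minutes on one
CPU while leaving every qualitative effect measurable; the full-size
crops, the 969-window grid and 11-member ensembles remain the defaults of
the respective functions.

## Experiments

`make_folds()` builds the six-fold plan (every case tested exactly once;
train = complement). Controlled comparisons (cost functions, combined
arms) share fold plans and initialisation seeds across arms so the factor
under study is the only difference. Aggregation is over all folds
combined, not per-fold means, with the sample SD (n − 1 denominator — the
package's choice where unstated). The combined experiment pairs, per test
case, a single model trained on the full training set against an ensemble
trained on the augmentation-doubled training set and evaluated under the
patient-specific window, with the ensemble majority vote acting as the
predictor the window search scores. The data-curation comparison is a
recipe rather than code: it needs two human-made contour sets per case,
which cannot be synthesised; `contour_complexity()` supports its analysis.

## Known limitations

* The trainer is a desk-scale backend, not a GPU framework; wall-clock
  scaling to clinical crop sizes is out of scope.
* The window search needs a reference mask (see above).
* The Hausdorff training penalty is non-differentiable; its gradient-free
  treatment means the combined cost shapes training only through epoch
  selection and the Dice term.
* Phantom effects sizes are not clinical effect sizes.
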