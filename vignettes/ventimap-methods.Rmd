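---
title: "Ventilation imaging from 4D thoracic CBCT: models, estimators and their verification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ventilation imaging from 4D thoracic CBCT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ventimap)
```

## The problem

Regional lung ventilation — how much each parcel of lung inflates over the
breathing cycle — can be imaged directly with aerosol SPECT, but that
modality is rarely available during a course of thoracic radiotherapy. 4D
phase-resolved cone-beam CT (ten respiratory bins `T00` … `T90`, with `T00`
peak inhale and `T50` peak exhale) is acquired routinely on the treatment
machine, and several surrogates derive a ventilation image (VI) from it:

* **Jacobian (JAC)**: deformably register peak inhale to peak exhale and map
  local volume change, `VI = det(I + ∇u) − 1`, where `u` is the displacement
  field on the exhale grid pointing to corresponding inhale positions.
* **Density change (HU)**: under the air–tissue mixture model, `1000 + HU` is
  proportional to tissue density, so comparing each exhale voxel's HU with
  the mean HU of its mapped inhale volume of interest `H̃` gives
  `VI = 1000·(H̃ − HU_ex) / (HU_ex · (1000 + H̃))`.
* **Learned (DL)**: a slice-based U-net regresses the ventilation image
  directly from the stack of phase images, trained against a reference
  ventilation map; no registration is involved at inference time.

All three share one post-processing chain (exhale lung masking, 90th-
percentile normalisation, box median filtering) and one evaluation protocol
(masked voxel-wise Spearman correlation against the reference, tertile
high/medium/low functional-lung segmentation compared by Dice, one-way ANOVA
with Tukey HSD across methods).

This package implements all of the above plus a synthetic breathing-lung
phantom with closed-form ground truth, so that every stage can be verified
against an analytic oracle rather than against unavailable clinical scans.

## The phantom

`phantom_spec()` describes a torso (elliptic cylinder, +40 HU) with two
ellipsoidal lungs (exhale baseline −800 HU) and a midline trachea (−1000
HU) on a default 96×96×64 grid at 2 mm. Breathing is a z-directed expansion
about a fixed apex plane `z0`:

\[ z \mapsto z_0 + (1 + w\,a(x, y))\,(z - z_0), \]

where `w ∈ [0, 1]` is the phase weight (cosine schedule over the ten bins:
1 at `T00`, 0 at `T50`) and `a(x, y)` the regional specific ventilation —
a base level `a0`, a dorsoventral gradient `a1`, and multiplicative Gaussian
ventilation defects. Because the displacement gradient is unit-lower-
triangular, the Jacobian determinant is **exactly** `1 + w·a(x, y)` inside
the lungs; `a(x, y)` is therefore the closed-form ground-truth ventilation.
This is what makes the phantom an anti-drift oracle: every estimator can be
checked against it to floating-point precision.

Lung HU follows air–tissue mass conservation across phases,
`(1000 + HU_w) = (1000 + HU_{ex} + T)/(1 + w a)`, where `T` is a smooth
vascular-like HU texture (default SD 50 HU, 5 mm correlation length)
attached to the tissue in material coordinates and scaled with density.
The texture serves two purposes: it is what makes intensity-based
registration of the phases well posed (homogeneous ellipsoids would carry
no interior motion information), and it is anatomically motivated
(pulmonary vessels and bronchi). Substituting the mass-conservation
relation into the density-change formula shows the two DIR estimators are
analytically tied on this phantom: `VI_HU = (1000/−HU_ex)·(J − 1)`, i.e.
`1.25 (J − 1)` at −800 HU — a relation the tests assert to 2 % at interior
lung voxels.

Measurement effects are added last and are the only stochastic parts:
per-phase Gaussian noise (default 20 HU), a smooth multiplicative shading
field (default 3 %, emulating CBCT nonuniformity), and a SPECT-like
degradation of the ground truth (`degrade_to_spect_like()`): Gaussian blur
at 4 mm, averaging onto a 4× coarser grid (≈8 mm, the SPECT/CBCT resolution
ratio), count-statistics noise with variance proportional to the local mean
(default 5 % relative — post-reconstruction aerosol-SPECT noise level,
chosen so that the reference retains rank agreement ≥ 0.8 with the truth),
clipping at zero, and trilinear interpolation back to the fine grid. The
blur uses normalised convolution inside the lung support: a plain
zero-padded blur drags boundary voxels toward zero so strongly that even a
noise-free reference loses most of its rank agreement with the truth,
which would make every downstream comparison meaningless.

What the phantom does **not** emulate: CBCT scatter/streak artifacts,
truncated fields of view, hysteresis between the inhale and exhale limbs,
sliding of the pleura against the chest wall (the analytic field tapers
smoothly over a 6 mm shell instead), tumours, and SPECT attenuation or
scatter physics. Passing tests on the phantom therefore demonstrate the
correctness of the estimators and statistics, not clinical-grade accuracy.

A cohort generator (`make_cohort()`) jitters lung geometry, expansion
parameters, defect placement and texture per subject (seeded,
reproducible); anatomy is controlled separately from measurement noise so
that two subjects with the same specification but different seeds share
identical truth.

## Deformable registration

Clinical workflows typically use closed-source commercial registration; in
its place this package provides a fully documented multiresolution demons
scheme (`demons_register()`): at each iteration the
moving image is backward-warped through the current field; the classical
normalised force `(f − m∘(id+u))·∇f / (|∇f|² + diff²/s²)` is Gaussian-
smoothed and added to the field; the accumulated field is smoothed again
(diffusion-like regularisation); levels run coarse to fine (default 3
levels, 50 iterations each, update/field smoothing 1 mm / 2 mm). Three
choices beyond the textbook scheme were needed, all exposed in
`registration_params()`:

* **Intensity-difference gating** (`diff_threshold`, default 1 HU). The
  normalised force is scale-invariant, so in flat regions where both the
  difference and the gradient are numerically tiny the update still attains
  near-maximal magnitude in an arbitrary direction; ungated, the
  registration diverges on piecewise-constant anatomy.
* **Lung-window density matching** (`density_match`). Inhale lung is
  systematically darker than exhale lung (that density change *is* the
  ventilation signal), so `1000 + HU` of the moving image is rescaled by
  one global factor estimated within the lung HU window before matching.
  Without it the ≈40 HU offset, multiplied by random texture gradients,
  produces incoherent forces; mean endpoint error on the phantom degrades
  from ≈1 mm to ≈4 mm.
* **Symmetric forces** (`symmetric_forces`): the mean of fixed and
  warped-moving gradients.

Direction convention: the fixed image is peak exhale; the field lives on
the exhale grid and points to inhale positions, so `J ≥ 1` in ventilated
lung and `J − 1` is nonnegative. (Read literally, projecting inhale onto
exhale would give `J ≤ 1` and negative ventilation; the convention that
yields nonnegative maps is adopted.)

On the noiseless textured phantom the scheme recovers the analytic field
with mean endpoint error ≈1 mm (half a voxel). The Jacobian of the
*recovered* field is a much harder target: a ≈1 mm displacement error
varying over centimetre scales produces derivative errors of the same
order as the entire ventilation signal (`a` spans ≈0.06–0.25), so the
ranking of the demons-derived `J − 1` against the truth is weak even when
the displacement itself is accurate. This package reports that number
honestly rather than engineering around it; it is the same phenomenon that
makes registration-based ventilation fragile on clinical data, where both
DIR methods correlate near chance with SPECT.

## The estimators

`ventilation_jacobian()` evaluates `det(I + ∇u) − 1` with spacing-aware
central differences (one-sided at the grid boundary); the stencil is exact
for fields affine in the coordinates, which the tests exploit
(`u = 0.1·x` → `J = 1.1³ = 1.331` to 1e−9).

`ventilation_density_change()` implements the density-change formula per
masked exhale voxel. The volume of interest of an exhale voxel is
discretised as the inhale voxel centres falling inside the bounding box of
the voxel cell's eight corners mapped through the field, with trilinear
sampling at the mapped centre as the fallback for empty boxes (local
contraction). Following the description of the VOI as a set of inhale
*lung* voxels, an optional inhale lung mask restricts the average; without
it, boundary VOIs mix in chest-wall tissue. Denominator guards zero the
voxels where `HU_ex ≈ 0` (vessels) or `H̃ ≈ −1000`; more than 10 % guarded
voxels aborts, since that indicates broken masking or registration.

`postprocess()` applies, in order: masking, division by the in-mask 90th
percentile (linear-interpolation percentile over in-mask voxels only — a
whole-image percentile would be dominated by the zeros outside the lung),
box median filtering (default 9³, reflect padding), re-masking. The order
(normalise, then filter) is pinned by a test so refactors cannot silently
swap it; scale invariance holds either way (to floating-point round-off of
the normalisation). The filter size is in
voxels and defaults to the 2 mm-grid value; runs on coarser grids should
use the physically matched odd size (e.g. 5 at 3–4 mm). The median filter
is evaluated only on the mask's padded bounding box, which is exact for
in-mask output and several times faster than filtering the full grid.

## The learned estimator

`build_unet()` constructs the slice-based U-net: an encoder of `depth`
blocks (two 3×3 convolutions with ReLU, dropout, 2×2 max-pool, filters
doubling from `base_filters`), a two-convolution bottleneck, a mirrored
decoder (2×2 up-sampling + 3×3 convolution + ReLU, skip concatenation, two
3×3 convolutions), and a head of one 3×3 convolution with ReLU and a 1×1
convolution (ReLU'd, since ventilation references are nonnegative counts).
Weights are He-normal initialised. Input modes: the ten phases as channels,
the two extreme phases, or the 2.5-D variant stacking each phase's slice
with its axial neighbours (30 channels). Inputs are scaled
`(HU + 1000)/1000` clipped to `[0, 2]`; labels are the subject's reference
map normalised by its in-mask 90th percentile. The network and its
backward pass are implemented directly in R on BLAS matrix multiplies
(im2col convolutions with the gather loop in C); a finite-difference
gradient check pins the implementation to ≈1e−7 relative error.

Training (`train()`) follows the standard recipe: RMSprop, initial learning
rate 1e−4, mini-batches of 4 slices, mean-squared-error loss, learning-rate
decay ×0.2 after 10 epochs without validation improvement, early stopping
after 15, weights restored from the best validation epoch, flips/rotations/
scalings/shifts as augmentation, and a *subject-level* 80/20
train/validation split — never by slice, so no patient's slices straddle
the split. `crossvalidate()` wraps the patient-level k-fold protocol
(default sevenfold) with an id audit asserting zero subject leakage.

Choices the architecture description leaves open, pinned here: depth 4 /
base 64 as the full-scale default with depth 3 / base 8 at the desk-scale
test size of 64×64 (CPU minutes instead of GPU hours); one dropout layer
(rate 0.2) after each encoder block; the rectified output unit's bias
initialised to 0.01 rather than 0 (a zero-initialised nonnegative head can
die for some seeds before it ever fires); whole-slice loss with labels
zeroed outside the lung by default, with a masked-loss option.

The desk-scale verification runs make two adaptations, both exposed as
ordinary configuration: the masked loss (with ≈100 training slices the
lung occupies ≈15 % of each slice, so the whole-slice loss spends most of
its budget reproducing background zeros while the ventilation pattern sits
an order of magnitude below the loss floor) and an initial learning rate
of 3e−4 instead of 1e−4 (the desk runs take ≈25 gradient steps per epoch
against the hundreds of a full-size training, and the default rate does
not converge within CPU minutes). The default configuration keeps the
full-scale recipe. With a six-subject training set the internal validation
split holds a single subject, whose loss is a noisy model-selection
signal; `train()` therefore returns the final-epoch weights
(`final_model`) alongside the best-validation weights, though the
best-validation protocol remains the default.

## Evaluation statistics

`spearman_masked()` ranks in-mask voxels only (average ranks on ties;
constant input raises an error instead of silently returning 0).
`tertile_segmentation()` thresholds at the in-mask 33⅓ and 66⅔ linear-
interpolation percentiles; ties go to the higher region, deterministically.
`dice_coefficient()` and `averaged_dsc()` implement the region overlap and
its three-region mean; two empty regions define Dice 1 with a warning
(impossible for valid tertiles, possible for user-supplied labels).
Independent random tertile maps give an averaged Dice of exactly 1/3 in
expectation — the chance level against which method scores should be read.
`anova_tukey()` is one-way ANOVA across methods on per-subject averaged
Dice with Tukey HSD pairwise adjusted p-values; a null-calibration test
checks the overall p-value is uniform over 200 seeded null replicates.

## Numerical choices and degenerate inputs

* Percentiles everywhere use the linear-interpolation definition
  (`type = 7`).
* Geometry equality is exact in shape and within 1e−6 mm in
  spacing/origin; physical position is `origin + index·spacing` (0-based),
  axial slices indexed by z.
* Resampling out-of-support fill defaults to the source minimum (air-like).
* Centre cropping breaks odd-margin ties toward the low index and shifts
  the origin so retained voxels keep their physical coordinates.
* Lung segmentation is the closed HU window `[−999, −250]`, then
  26-connected components; components touching the in-plane border are
  discarded as background air, components whose centroid falls in a
  configurable midline corridor (default half-width 15 % of the x extent)
  are discarded as central airways, and the two largest survivors are the
  lungs.
* Empty masks, constant images (undefined correlations/tertiles),
  non-overlapping grids, and single-subject splits raise classed errors
  rather than producing numbers.

## Problem sizes used in the checks

The verification suite runs on one CPU: closed-form phantom checks at
96×96×64 (2 mm); registration recovery at the same size; learning-mechanism
checks on 64×64×32 subjects at (3, 3, 4) mm with depth 3 / base 8 — an
8-subject cohort with 6 training subjects, and a separate 8-slice
overfitting run; statistical calibrations at 10⁴ voxels and 200 null
replicates. The cross-validation harness logic is exercised on 28 subject
ids with k = 7 (fold assembly and leakage audit are independent of
training cost).

## Known limitations

The demons-derived Jacobian ranks ventilation weakly even at ≈1 mm
registration error (see above) — on this phantom as on clinical data, the
displacement field is recoverable but its derivative is not a reliable
ventilation surrogate. The phantom's breathing is single-axis and
hysteresis-free, so registration here is easier than on real 4D-CBCT; the
learned estimator's phantom scores say nothing about clinical accuracy and
the clinical headline numbers are not reproducible without the patient
data. MetaImage support covers the common scalar subset (MET_UCHAR/SHORT/
FLOAT/DOUBLE, local or detached raw, little-endian). The R implementation
of the U-net is CPU-bound and desk-scale by design.
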