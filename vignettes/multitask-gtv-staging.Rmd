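---
title: "Joint GTV segmentation and T-staging: model, phantoms and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint GTV segmentation and T-staging: model, phantoms and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Nasopharyngeal carcinoma is staged by how far the primary tumor invades
surrounding structures (T1--T4), and treated by radiotherapy planned on a
delineated gross tumor volume (GTV).  Both tasks read the same
contrast-enhanced T1-weighted MR volume, and both depend on the same
underlying quantity — the tumor's spatial extent.  `gtvstage` implements a
multi-task network that produces the GTV segmentation and the T-stage
probability vector simultaneously from a single 3D volume, together with a
synthetic phantom generator that makes the whole pipeline testable without
clinical data, and the metric/statistics stack used to evaluate it.

## Model

Three components are trained end to end:

1. **Segmentation network.** A U-shaped 3D encoder--decoder with eight
   encoder units and seven decoder units.  Each unit is a 3x3x3 convolution
   with per-channel instance normalisation and ReLU; pooling steps (max
   in-plane, average across slices, factors of 2) downsample on the
   contracting path and nearest-neighbour upsampling with skip
   concatenations mirror them on the expanding path.  A 1x1x1 convolution
   and sigmoid produce the voxelwise tumor probability map.
2. **Staging backbone.** The probability map multiplies the input volume
   (a soft gate) and the gated volume enters a 4-stage residual network
   whose final three bottleneck blocks replace their spatial convolution
   with 4-head self-attention over the feature grid — a bottleneck
   transformer.  Per head, attention logits are the scaled sum of a content
   term `q k'` and a position term `q p'`, with factorised learned per-axis
   position encodings summed over the three axes.
3. **Feature-fusion-aware (FFA) module.** The three most semantic
   segmentation feature maps — the seventh and eighth encoder outputs and
   the first decoder output, at the bottom of the U — are projected by
   1x1x1 convolutions, resized (trilinearly) to the backbone grid,
   concatenated with the backbone features, and mixed by a residual
   multi-head self-attention block.  Global average pooling, an affine map
   and a softmax yield the four stage probabilities.  The `wo_ffa` ablation
   replaces the attention mixing with plain concatenation; the `separate`
   ablation trains segmentation first, freezes it, and then trains the
   staging branch on its detached output.

### Objective

The combined loss is `lambda_seg * L_seg + lambda_cls * L_cls`, where
`L_seg` is the unweighted sum of a soft Jaccard loss (smoothing eps = 1)
and a focal loss (gamma = 2, alpha = 0.75 on the foreground class), and
`L_cls` is cross-entropy over the four stages.  The task weights are
trainable: we adopt homoscedastic-uncertainty weighting,
`total = exp(-s_seg) L_seg + s_seg + exp(-s_cls) L_cls + s_cls`, with both
log-precisions initialised to 0 so both effective weights start at exactly
1 and are updated by gradient during training.  A fixed-weight mode is
available (`weight_mode = "fixed"`).  For a fixed component value `L`, the
optimum of `exp(-s) L + s` is `s* = log L`, i.e. the weight settles at
`1/L` — noisier tasks are automatically down-weighted.

Two focal-loss choices deviate from common detection defaults and deserve
a note.  With 1--5% foreground voxels, `alpha = 0.25` (the detection
convention) suppresses the already-rare tumor class; we default to
`alpha = 0.75` so the foreground carries three times the background's
weight.  The segmentation output bias is initialised to the logit of a
small foreground prior (-2.9) so the initial map predicts mostly
background, the standard initialisation for rare-foreground focal
training.

### Cross-task gradient flow

The gate multiply and the feature taps create a differentiable path from
the staging loss back into the segmentation network — deliberately so, as
this is the mechanism of multi-task synergy.  Numerically, however, that
path amplifies gradients: the gated volume has tiny variance, the
backbone's instance norms rescale it to unit variance, and their backward
passes multiply the incoming gradient by the same large factors.  At desk
scale we measured staging-loss gradients into segmentation weights three
to four orders of magnitude larger than the segmentation loss's own, which
freezes segmentation learning entirely.  `net_config(cross_clip = 0.1)`
therefore bounds the *norm* of the gradient flowing back through each of
the four task interfaces (gate plus three taps).  The forward computation
is untouched, the path remains differentiable, and setting
`cross_clip = 0` recovers the raw gradients (the suite's finite-difference
gradient checks run in that mode).

## Synthetic phantoms

The generator emulates the statistical structure the model must exploit,
not MR physics:

* a "head" of nested ellipsoidal shells — core cavity (label 1, the
  nasopharynx) and three progressively deeper bands (2--4) — on an
  anisotropic grid, by default 16x64x64 voxels at (6, 0.5, 0.5) mm;
* a connected tumor grown from the inner core by randomized
  6-neighbourhood accretion, with frontier voxels drawn proportionally to
  the inverse spacing of the face crossed, so growth is approximately
  isotropic in millimetres;
* a stage label defined *only* through geometry: the deepest band whose
  cumulative overlap fraction (|mask in bands >= b| / |mask|) reaches the
  invasion threshold (default 0.05), else stage 1.  Cumulative fractions
  keep the rule monotone — enlarging a tumor at or beyond its current
  depth can never lower its stage.  Every emitted label is recomputed from
  the emitted mask;
* per-stage tumor volume ranges (60--140, 250--700, 1300--2600, 4200--6500
  voxels) calibrated once against the shell geometry so that the wanted
  stage is realised with high acceptance, with the stage mixture defaulting
  to the clinical imbalance (8/44/27/21%);
* image = base intensity + low-frequency Gaussian random-field texture
  (amplitude 0.3, outside the tumor) + smooth bias field (amplitude 0.2) +
  additive tumor contrast (1.0) + Gaussian noise (sd 0.2).  Texture below
  contrast keeps pure thresholding imperfect while leaving the task
  learnable in minutes of CPU time.

What the phantoms do *not* model: Rician noise physics, multi-sequence
appearance, anatomically realistic boundaries, or inter-observer contour
variability.  Passing tests therefore demonstrate that the implementation
learns and evaluates correctly on data with the right dependence structure
(stage determined by anatomical extent), not that it reaches clinical
performance on real MRI.

## Preprocessing

The chain mirrors clinical practice: resample to a common target spacing
(third-order spline in-plane, nearest neighbour across slices; nearest
everywhere for masks, which therefore stay strictly binary), z-score
normalise (subtract mean, divide by population SD), and crop or zero-pad
to the network grid.  The crop is centred on the mask centroid when a mask
is available (training) and on the volume centre otherwise (inference);
normalisation happens after resampling and before cropping by default,
with `pre_config(normalize = "after_crop")` available.  Internal axis
order is (slice, row, column) throughout, so the clinical target
resolution of 0.4688 mm in-plane and 6 mm between slices is written
`c(6, 0.4688, 0.4688)`.  Splits are stratified: within every stage, fold
sizes differ by at most one case.

## Problem sizes and training protocol

Defaults in `train_config()` follow the clinical protocol: Adam, batch 4,
learning rate 2e-4, ReduceLROnPlateau (factor 0.2, patience 10), stop at
learning rate < 1e-9 or 300 epochs, augmentation by random in-plane flips,
+/-10 degree nearest-neighbour rotations and +/-10% intensity scaling, and
best-validation-loss checkpointing.  The scheduler's factor/patience and
the checkpoint criterion are this package's choices; the protocol leaves
them open.

The desk-scale experiments reported by `run_ablation_study()` and the
acceptance script use sizes chosen once for single-CPU minutes: 100-case
cohorts on the 16x64x64 grid, resampled to (6, 1, 1) mm and cropped to
10x24x24, the tiny default `net_config()` (about 185k parameters), 5
epochs per fold at learning rate 3e-3, stratified 3-fold cross-validation,
and 5 seeds for the ablation comparison.  Within a seed, the full model
and both ablations share the cohort, the split, the shuffling and the
epoch budget, so mode comparisons are paired by construction and are
assessed on paired per-seed differences.

## Numerical choices

* Dice is `2|A n G| / (|A| + |G|)`, defined as 1 when both masks are empty
  and 0 when exactly one is.  Average surface distance is the symmetric
  mean over both directions of surface-voxel distances (6-neighbourhood
  surfaces; array borders count as background), computed by an exact
  anisotropic Euclidean distance transform in millimetres, and undefined
  (excluded, with a warning) for empty masks.
* Cohort summaries use interpolated quartiles and a seeded bootstrap CI of
  the median (10,000 resamples by default).
* Sensitivity/specificity for the 4-class problem are macro-averaged
  one-vs-rest reductions; accuracy carries a Clopper-Pearson interval.
  Multiclass AUC is one-vs-rest with mid-rank tie handling, micro or
  macro; the DeLong comparison applies to the micro construction.
* Exact small-sample paths: signed-rank enumeration up to n = 25 (without
  ties), rank-sum enumeration when the smaller sample has at most 8,
  McNemar's doubled binomial tail below 25 discordant pairs; beyond these,
  tie- and continuity-corrected normal approximations (continuity-corrected
  chi-square for McNemar).  Pearson's chi-square is used without continuity
  correction, which reproduces the printed cohort-comparison p-values
  exactly.
* Resampling maps output index `i` to input coordinate
  `i * target/native`; the cubic kernel is Catmull-Rom with linearly
  extrapolated border samples, so constants and linear ramps are
  reproduced exactly.
* Degenerate inputs fail loudly: constant volumes cannot be z-normalised,
  empty masks cannot be staged, non-finite loss components abort with
  diagnostics, and checkpoints refuse to load into a mismatched
  architecture (fingerprint check).

## Known limitations

* The phantom's intensity statistics are uncalibrated against any clinical
  cohort — the generator's parameters are free configuration, not claims
  about real data.
* Desk-scale training budgets (minutes, not GPU-days) leave the
  segmentation boundary coarse; at these budgets the median phantom Dice
  sits near 0.5--0.6, far below what full-scale training reaches.
* The full-vs-ablation staging differences at phantom scale are small
  relative to seed noise; only their paired ordering, not their magnitude,
  is meaningful.
* Single-sequence input only; nodal staging and multi-sequence fusion are
  out of scope.
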