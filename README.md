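# gtvstage

Joint gross-tumor-volume (GTV) segmentation and T-staging of
nasopharyngeal carcinoma from a single contrast-enhanced 3D MR volume.

Radiotherapy planning needs the GTV contour; treatment selection needs the
T stage (T1–T4, the local-invasion component of TNM staging).  Both are
read from the same volume and both hinge on the tumor's spatial extent, so
`gtvstage` models them jointly: a U-shaped 3D segmentation network
produces a voxelwise tumor probability map p̂; the map gates the input
volume (elementwise product) for a bottleneck-transformer staging backbone
— a 4-stage residual network whose final three bottleneck blocks use
4-head self-attention with factorised 3D position encodings; and a
feature-fusion-aware module mixes the three bottom-of-U segmentation
feature taps with the backbone features through a residual attention block
before a softmax classifier outputs the stage probabilities ŷ.  Training
minimises

    L = λ_Seg · L_Seg(p, p̂) + λ_Cls · L_Cls(y, ŷ)

with `L_Seg` = soft Jaccard + focal loss, `L_Cls` = cross-entropy, and
trainable task weights λ (homoscedastic-uncertainty parameterisation,
both initialised to 1).

Because the clinical cohorts behind this design are private, the package
ships a synthetic phantom generator whose ground-truth stage is a pure
function of simulated anatomical invasion: nested ellipsoidal shells form
a "head", a connected tumor grows stochastically from the core cavity, and
the stage is the deepest shell the tumor invades.  Every component —
preprocessing (spline resampling, z-scoring, crop/pad, stratified
3-fold splits), training (Adam, ReduceLROnPlateau, flip/rotation/intensity
augmentation, two ablation protocols), metrics (Dice, anisotropic average
surface distance) and statistics (Clopper–Pearson intervals, one-vs-rest
micro/macro AUC, DeLong, McNemar, Wilcoxon, Mann–Whitney, chi-square) — is
exercised end to end on those phantoms.

The audience is methods researchers in medical image analysis who want a
fully inspectable, dependency-light reference implementation of the
multi-task architecture and its evaluation stack, in R.

## Worked example

```r
library(gtvstage)

co <- generate_cohort(phantom_config(), n = 100, seed = 1)
print(co)
cases <- prep_cohort(co$cases)
cv <- run_cv(cases, k = 3,
             config = train_config(max_epochs = 5, lr = 3e-3, seed = 1))
print(cv)
summary(cv)
```

prints (about five minutes on one CPU):

```
Phantom cohort: 100 cases on a 16x64x64 grid @ (6, 0.5, 0.5) mm
stage
 1  2  3  4
 4 42 26 28
3-fold cross-validation, 100 pooled out-of-fold cases
  pooled ACC 0.660 | micro-AUC 0.877 | median DSC 0.583
Cohort report, n = 100
  ACC 0.66 (66 of 100; 95% CI: 0.56, 0.75)
  SEN 0.56 | SPE 0.88 | AUC micro 0.88 | macro 0.83
 metric    median       iqr
    dsc 0.5830468 0.2967251
 asd_mm 0.8453866 0.8488290
```

Reading: on 100 synthetic cases the model never saw (each predicted by the
fold that held it out), staging reaches 0.66 accuracy with its exact
binomial interval and 0.88 micro-average one-vs-rest AUC, while the median
out-of-fold Dice overlap with the true tumor is 0.58 and the median
surface error is 0.85 mm.  Per-case prediction:

```r
pr <- predict(cv$fits[[1]], co$cases[[2]])
# case_0002: true stage T4, predicted T4, DSC 0.33
```

The two ablations of the multi-task design are one call away:
`run_ablation_study()` repeats the cross-validation for the full model,
the fusion-without-attention variant (`wo_ffa`) and two-phase decoupled
training (`separate`) on identical cohorts, splits and budgets.

A thin command-line front end (`inst/cli/gtvstage`) wraps cohort
generation, training, cross-validation and prediction for shell use, with
NIfTI volumes and CSV manifests as the interchange formats.

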