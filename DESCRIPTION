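Package: gtvstage
Title: Joint Gross Tumor Volume Segmentation and T-Staging of
    Nasopharyngeal Carcinoma from 3D MR Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A multi-task model that simultaneously delineates the gross
    tumor volume (GTV) of nasopharyngeal carcinoma and predicts its T
    stage from a single contrast-enhanced 3D MR volume.  A U-shaped 3D
    segmentation network gates a bottleneck-transformer staging backbone
    through a feature-fusion-aware attention module; both tasks are
    optimised jointly under a combined Jaccard/focal + cross-entropy
    objective with trainable task weights.  Ships a synthetic 3D phantom
    generator whose stage labels are tied to simulated anatomical
    invasion, the full preprocessing chain (spline resampling, z-score
    normalisation, crop/pad, stratified k-fold splitting), segmentation
    metrics (Dice, anisotropic average surface distance), and the
    cohort-level statistics suite (Clopper-Pearson intervals,
    one-vs-rest ROC-AUC, DeLong, McNemar, Wilcoxon, Mann-Whitney,
    chi-square).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
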