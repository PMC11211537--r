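# Multi-task objective: L = lambda_seg * L_seg + lambda_cls * L_cls, where
# L_seg is soft Jaccard + focal loss on the probability map and L_cls is
# cross-entropy over the four stages.  The task weights are trainable: under
# the default homoscedastic-uncertainty parameterisation, lambda = exp(-s)
# with trainable log-precision s (initialised 0, so both weights start at 1)
# and an additive +s regulariser that keeps the optimum finite.

#' Soft Jaccard segmentation loss
#'
#' `1 - (sum(p*t) + eps) / (sum(p) + sum(t) - sum(p*t) + eps)` with
#' smoothing `eps = 1` stabilising empty-mask batches.
#'
#' @param pred probability volume in `[0,1]`.
#' @param truth binary volume of the same shape.
#' @param eps smoothing constant.
#' @return scalar loss.
#' @export
soft_jaccard_loss <- function(pred, truth, eps = 1) {
  if (!identical(dim(pred), dim(truth))) stop("shape mismatch")
  i <- sum(pred * truth)
  u <- sum(pred) + sum(truth) - i
  1 - (i + eps) / (u + eps)
}

#' Focal loss for voxelwise binary segmentation
#'
#' Mean over voxels of `-alpha_t * (1 - p_t)^gamma * log(p_t)` where `p_t`
#' is the predicted probability of the true class and `alpha_t` is `alpha`
#' for foreground, `1 - alpha` for background.  The default `alpha = 0.75`
#' upweights the rare foreground class.  With `gamma = 0` it reduces to
#' alpha-weighted binary cross-entropy.
#'
#' @param pred probability volume; values are clamped to
#'   `[clip, 1 - clip]`.
#' @param truth binary volume.
#' @param gamma focusing exponent (default 2).
#' @param alpha foreground weight (default 0.75).
#' @param clip probability clamp.
#' @return scalar loss.
#' @export
focal_loss <- function(pred, truth, gamma = 2, alpha = 0.75, clip = 1e-7) {
  if (!identical(dim(pred), dim(truth))) stop("shape mismatch")
  p <- pmin(pmax(pred, clip), 1 - clip)
  pt <- ifelse(truth == 1, p, 1 - p)
  at <- ifelse(truth == 1, alpha, 1 - alpha)
  mean(-at * (1 - pt)^gamma * log(pt))
}

#' Cross-entropy classification loss
#'
#' `-log(probs[label])` for a 4-way stage probability vector.
#'
#' @param probs probability vector (nonnegative, sums to 1).
#' @param label integer stage in 1..length(probs).
#' @return scalar loss.
#' @export
cross_entropy_cls <- function(probs, label) {
  if (label < 1 || label > length(probs) || label != round(label))
    stop("label outside 1-", length(probs))
  -log(max(probs[label], 1e-12))
}

#' Loss weight state
#'
#' Trainable task-weight scalars.  Under `parameterization = "uncertainty"`
#' the stored values are log-precisions `s` with effective weight
#' `lambda = exp(-s)`; both start at `s = 0`, i.e. `lambda = 1`.  Under
#' `"fixed"` the weights are plain constants.
#'
#' @param parameterization `"uncertainty"` or `"fixed"`.
#' @param lambda_seg,lambda_cls initial effective weights.
#' @return object of class `loss_weights`.
#' @export
loss_weights <- function(parameterization = c("uncertainty", "fixed"),
                         lambda_seg = 1, lambda_cls = 1) {
  parameterization <- match.arg(parameterization)
  stopifnot(lambda_seg > 0, lambda_cls > 0)
  structure(list(parameterization = parameterization,
                 s_seg = -log(lambda_seg), s_cls = -log(lambda_cls)),
            class = "loss_weights")
}

#' Combined multi-task loss
#'
#' Composes the segmentation terms (Jaccard + focal, unweighted sum) and the
#' classification cross-entropy under the trainable task weights.  With the
#' uncertainty parameterisation the total is
#' `exp(-s_seg) L_seg + s_seg + exp(-s_cls) L_cls + s_cls`; at
#' initialisation (`s = 0`) this equals `L_seg + L_cls`.
#'
#' @param jaccard,focal,cls scalar loss components.
#' @param weights a [loss_weights()] object.
#' @return a `loss_breakdown` list: `total`, `seg_component`,
#'   `cls_component`, `jaccard`, `focal`, `lambda_seg`, `lambda_cls`.
#' @export
combined_loss <- function(jaccard, focal, cls, weights = loss_weights()) {
  comps <- c(jaccard, focal, cls)
  if (any(!is.finite(comps)))
    stop("non-finite loss component: jaccard=", jaccard, " focal=", focal,
         " cls=", cls)
  l_seg <- jaccard + focal
  if (weights$parameterization == "uncertainty") {
    ws <- exp(-weights$s_seg); wc <- exp(-weights$s_cls)
    total <- ws * l_seg + weights$s_seg + wc * cls + weights$s_cls
  } else {
    ws <- exp(-weights$s_seg); wc <- exp(-weights$s_cls)
    total <- ws * l_seg + wc * cls
  }
  structure(list(total = total, seg_component = l_seg, cls_component = cls,
                 jaccard = jaccard, focal = focal,
                 lambda_seg = exp(-weights$s_seg),
                 lambda_cls = exp(-weights$s_cls)),
            class = "loss_breakdown")
}
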