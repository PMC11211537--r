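# Training orchestration: single-fold fitting, stratified three-fold
# cross-validation with pooled out-of-fold predictions, and the two
# ablation protocols (separate two-phase training; fusion without
# attention).  Optimiser is Adam on the combined multi-task loss with
# ReduceLROnPlateau scheduling; a run stops when the learning rate falls
# below `min_lr` or after `max_epochs`.

#' Training configuration
#'
#' @param batch_size cases per optimiser step.
#' @param lr initial learning rate.
#' @param sched_factor multiplicative learning-rate decay on plateau.
#' @param sched_patience epochs without validation-loss improvement before
#'   the rate is reduced.
#' @param sched_min_delta minimum improvement that resets the plateau
#'   counter.
#' @param min_lr stopping threshold for the learning rate.
#' @param max_epochs epoch budget.
#' @param augment list of toggles: `flip` (random in-plane flips),
#'   `rotate` (in-plane rotation up to +/- `rotate_deg` degrees,
#'   nearest-neighbour), `intensity` (global intensity scale +/- 10%).
#' @param rotate_deg rotation range in degrees.
#' @param weight_mode `"uncertainty"` (trainable task weights,
#'   lambda = exp(-s) starting at 1) or `"fixed"`.
#' @param mode training protocol: `"full"`, `"separate"`, `"wo_ffa"`.
#' @param seed integer seed controlling initialisation, shuffling and
#'   augmentation.
#' @param log_csv optional path; per-step loss components are appended as
#'   `step,seg_loss,cls_loss,lambda_seg,lambda_cls,total`.
#' @return object of class `train_config`.
#' @export
train_config <- function(batch_size = 4L, lr = 2e-4,
                         sched_factor = 0.2, sched_patience = 10L,
                         sched_min_delta = 1e-4, min_lr = 1e-9,
                         max_epochs = 300L,
                         augment = list(flip = TRUE, rotate = TRUE,
                                        intensity = TRUE),
                         rotate_deg = 10,
                         weight_mode = c("uncertainty", "fixed"),
                         mode = c("full", "separate", "wo_ffa"),
                         seed = 1L, log_csv = NULL) {
  weight_mode <- match.arg(weight_mode)
  mode <- match.arg(mode)
  stopifnot(batch_size >= 1L, lr > min_lr, max_epochs >= 1L)
  structure(list(batch_size = as.integer(batch_size), lr = lr,
                 sched_factor = sched_factor,
                 sched_patience = as.integer(sched_patience),
                 sched_min_delta = sched_min_delta, min_lr = min_lr,
                 max_epochs = as.integer(max_epochs), augment = augment,
                 rotate_deg = rotate_deg, weight_mode = weight_mode,
                 mode = mode, seed = as.integer(seed), log_csv = log_csv),
            class = "train_config")
}

# ---- augmentation -----------------------------------------------------------

.aug_flip <- function(img, msk) {
  if (stats::runif(1) < 0.5) {
    img <- img[, rev(seq_len(dim(img)[2])), , drop = FALSE]
    msk <- msk[, rev(seq_len(dim(msk)[2])), , drop = FALSE]
  }
  if (stats::runif(1) < 0.5) {
    img <- img[, , rev(seq_len(dim(img)[3])), drop = FALSE]
    msk <- msk[, , rev(seq_len(dim(msk)[3])), drop = FALSE]
  }
  list(img = img, msk = msk)
}

.aug_rotate <- function(img, msk, deg_max) {
  th <- stats::runif(1, -deg_max, deg_max) * pi / 180
  dims <- dim(img)
  H <- dims[2]; W <- dims[3]
  ch <- (H + 1) / 2; cw <- (W + 1) / 2
  g <- expand.grid(h = seq_len(H), w = seq_len(W))
  hs <- round(ch + cos(th) * (g$h - ch) - sin(th) * (g$w - cw))
  ws <- round(cw + sin(th) * (g$h - ch) + cos(th) * (g$w - cw))
  ok <- hs >= 1 & hs <= H & ws >= 1 & ws <= W
  oi <- array(0, dims); om <- array(0L, dims)
  sel <- cbind(g$h[ok], g$w[ok])
  src <- cbind(hs[ok], ws[ok])
  for (d in seq_len(dims[1])) {
    si <- img[d, , ]; sm <- msk[d, , ]
    ti <- matrix(0, H, W); tm <- matrix(0L, H, W)
    ti[sel] <- si[src]; tm[sel] <- sm[src]
    oi[d, , ] <- ti; om[d, , ] <- tm
  }
  list(img = oi, msk = om)
}

.augment_case <- function(img, msk, cfg) {
  if (isTRUE(cfg$augment$flip)) {
    r <- .aug_flip(img, msk); img <- r$img; msk <- r$msk
  }
  if (isTRUE(cfg$augment$rotate)) {
    r <- .aug_rotate(img, msk, cfg$rotate_deg); img <- r$img; msk <- r$msk
  }
  if (isTRUE(cfg$augment$intensity))
    img <- img * stats::runif(1, 0.9, 1.1)
  list(img = img, msk = msk)
}

# ---- optimiser --------------------------------------------------------------

.adam_state <- function(params)
  list(m = lapply(params, function(p) p$value * 0),
       v = lapply(params, function(p) p$value * 0), t = 0L)

.adam_step <- function(params, st, lr, trainable, nbatch,
                       b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  for (nm in trainable) {
    p <- params[[nm]]
    g <- p$grad
    if (is.null(g)) next
    g <- g / nbatch
    st$m[[nm]] <- b1 * st$m[[nm]] + (1 - b1) * g
    st$v[[nm]] <- b2 * st$v[[nm]] + (1 - b2) * g * g
    mh <- st$m[[nm]] / (1 - b1^st$t)
    vh <- st$v[[nm]] / (1 - b2^st$t)
    p$value <- p$value - lr * mh / (sqrt(vh) + eps)
  }
  st
}

# ---- loss assembly ----------------------------------------------------------

# returns list(total node, seg, cls numeric components)
.case_loss <- function(tape, model, prep, sw, phase, cfg, training = TRUE) {
  mask4 <- array(prep$mask, c(1L, dim(prep$mask)))
  if (phase == "seg") {
    x <- ag_const(array(prep$image, c(1L, dim(prep$image))))
    seg <- .seg_forward_nodes(tape, x, model$params, model$config)
    jac <- ag_jaccard_loss(tape, seg$prob, mask4)
    foc <- ag_focal_loss(tape, seg$prob, mask4)
    total <- ag_add(tape, jac, foc)
    return(list(total = total, seg = jac$value + foc$value, cls = NA_real_,
                prob = seg$prob$value))
  }
  fw <- .mt_forward_nodes(tape, model, prep$image, training = training,
                          detach_seg = (phase == "cls"))
  ce <- ag_ce_loss(tape, fw$cls$probs, prep$stage)
  if (phase == "cls") {
    return(list(total = ce, seg = NA_real_, cls = ce$value,
                prob = fw$seg$prob$value, probs = fw$cls$probs$value))
  }
  jac <- ag_jaccard_loss(tape, fw$seg$prob, mask4)
  foc <- ag_focal_loss(tape, fw$seg$prob, mask4)
  lseg <- ag_add(tape, jac, foc)
  total <- if (cfg$weight_mode == "uncertainty")
    ag_uncertainty_sum(tape, lseg, ce, sw$s_seg, sw$s_cls)
  else ag_weighted_sum(tape, lseg, ce, exp(-sw$s_seg$value),
                       exp(-sw$s_cls$value))
  list(total = total, seg = lseg$value, cls = ce$value,
       prob = fw$seg$prob$value, probs = fw$cls$probs$value)
}

# ---- core fitting routine ---------------------------------------------------

#' Fit the multi-task model
#'
#' Trains on `train_cases`, monitors `val_cases` each epoch, reduces the
#' learning rate on validation-loss plateaus and retains the
#' best-validation checkpoint.  `mode = "separate"` trains the segmentation
#' network alone for the first half of the epoch budget, then freezes it
#' and trains the staging branch on its (detached) output; `"wo_ffa"` fuses
#' features by plain concatenation without attention.
#'
#' @param train_cases,val_cases lists of phantom cases (or any objects with
#'   `image`, `mask`, `stage`, `spacing`).
#' @param net a [net_config()].
#' @param pre a [pre_config()].
#' @param config a [train_config()]; its `mode` selects the protocol.
#' @return object of class `mt_fit`: fitted `model` (best-validation
#'   weights), `history` data frame, `stop_reason`, `best_epoch`,
#'   `weights` ([loss_weights()] state), configs.
#' @export
mt_fit <- function(train_cases, val_cases, net = net_config(),
                   pre = pre_config(), config = train_config()) {
  mode <- config$mode
  force(config)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(config$seed)
  tr <- lapply(train_cases, .prep_case, pre = pre, use_centroid = TRUE)
  va <- lapply(val_cases, .prep_case, pre = pre, use_centroid = FALSE)
  stg <- vapply(tr, `[[`, integer(1), "stage")
  if (any(tabulate(stg, 4L) == 0L))
    warning("a stage class is absent from the training portion")
  model <- mt_model(net, seed = config$seed, mode = mode)
  sw <- list(s_seg = ag_param(0), s_cls = ag_param(0))
  opt_all <- c(model$params, sw)
  ast <- .adam_state(opt_all)
  seg_names <- grep("^seg\\.", names(model$params), value = TRUE)
  lr <- config$lr
  best <- Inf; best_epoch <- 0L; best_values <- NULL
  plateau <- 0L
  stop_reason <- "max_epochs"
  hist <- list()
  phase_split <- if (mode == "separate")
    as.integer(ceiling(config$max_epochs / 2)) else config$max_epochs
  step <- 0L
  if (!is.null(config$log_csv))
    cat("step,seg_loss,cls_loss,lambda_seg,lambda_cls,total\n",
        file = config$log_csv)
  for (epoch in seq_len(config$max_epochs)) {
    phase <- if (mode != "separate") "joint"
             else if (epoch <= phase_split) "seg" else "cls"
    trainable <- switch(phase,
      joint = names(opt_all),
      seg = c(seg_names, "s_seg"),
      cls = c(setdiff(names(model$params), seg_names), "s_cls"))
    ord <- sample.int(length(tr))
    nb <- 0L
    tot_train <- 0
    for (ci in ord) {
      prep <- tr[[ci]]
      aug <- .augment_case(prep$image, prep$mask, config)
      prep <- list(image = aug$img, mask = aug$msk, stage = prep$stage)
      tape <- ag_tape()
      l <- .case_loss(tape, model, prep, sw, phase, config)
      ag_backward(tape, l$total)
      tot_train <- tot_train + l$total$value
      nb <- nb + 1L
      step <- step + 1L
      if (!is.null(config$log_csv))
        cat(sprintf("%d,%s,%s,%.6g,%.6g,%.6g\n", step,
                    format(l$seg), format(l$cls),
                    exp(-sw$s_seg$value), exp(-sw$s_cls$value),
                    l$total$value),
            file = config$log_csv, append = TRUE)
      if (nb == config$batch_size) {
        ast <- .adam_step(opt_all, ast, lr, trainable, nb)
        ag_zero_grad(opt_all)
        nb <- 0L
      }
    }
    if (nb > 0L) {
      ast <- .adam_step(opt_all, ast, lr, trainable, nb)
      ag_zero_grad(opt_all)
    }
    # validation pass (no tape, no augmentation)
    vtot <- 0; vd <- numeric(0); vacc <- numeric(0)
    for (vc in va) {
      l <- .case_loss(NULL, model, vc, sw, phase, config, training = FALSE)
      vtot <- vtot + l$total$value
      pm <- array(l$prob, dim(vc$mask))
      vd <- c(vd, as.numeric(dsc(pm >= 0.5, vc$mask)))
      if (!is.null(l$probs))
        vacc <- c(vacc, as.integer(which.max(l$probs) == vc$stage))
    }
    vtot <- vtot / max(1L, length(va))
    hist[[epoch]] <- data.frame(
      epoch = epoch, phase = phase,
      train_loss = tot_train / length(tr), val_loss = vtot,
      val_dsc = if (length(vd)) mean(vd) else NA_real_,
      val_acc = if (length(vacc)) mean(vacc) else NA_real_,
      lr = lr, lambda_seg = exp(-sw$s_seg$value),
      lambda_cls = exp(-sw$s_cls$value))
    if (vtot + config$sched_min_delta < best) {
      best <- vtot; best_epoch <- epoch; plateau <- 0L
      best_values <- lapply(model$params, function(p) p$value)
    } else {
      plateau <- plateau + 1L
      if (plateau > config$sched_patience) {
        lr <- lr * config$sched_factor
        plateau <- 0L
      }
    }
    if (lr < config$min_lr) { stop_reason <- "min_lr"; break }
    if (mode == "separate" && epoch == phase_split) {
      # entering phase 2: reset scheduling state for the new objective
      best <- Inf; plateau <- 0L; lr <- config$lr
      best_values <- NULL
    }
  }
  if (!is.null(best_values))
    for (nm in names(best_values)) model$params[[nm]]$value <- best_values[[nm]]
  structure(list(model = model, history = do.call(rbind, hist),
                 stop_reason = stop_reason, best_epoch = best_epoch,
                 weights = list(s_seg = sw$s_seg$value,
                                s_cls = sw$s_cls$value),
                 net = net, pre = pre, config = config, mode = mode),
            class = "mt_fit")
}

#' @export
print.mt_fit <- function(x, ...) {
  h <- x$history
  cat(sprintf("Multi-task fit (%s): %d epochs, stop: %s\n", x$mode,
              nrow(h), x$stop_reason))
  cat(sprintf("  final val loss %.4f | val DSC %.3f | val ACC %s\n",
              h$val_loss[nrow(h)], h$val_dsc[nrow(h)],
              ifelse(is.na(h$val_acc[nrow(h)]), "NA",
                     sprintf("%.3f", h$val_acc[nrow(h)]))))
  invisible(x)
}

#' @export
summary.mt_fit <- function(object, ...) {
  print(object)
  print(utils::tail(object$history, 3), row.names = FALSE)
  invisible(object$history)
}

#' @export
plot.mt_fit <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("grey40", "firebrick"),
                    xlab = "epoch", ylab = "loss", ...)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("grey40", "firebrick"), bty = "n")
  invisible(x)
}

#' Train one cross-validation fold
#'
#' Cases whose fold equals `fold` form the validation set; the rest train.
#'
#' @param cases list of phantom cases.
#' @param split a [stratified_kfold()] assignment over `cases`.
#' @param fold fold index in `0..k-1`.
#' @param net,pre,config see [mt_fit()].
#' @return an `mt_fit`, with the fold index attached.
#' @export
train_fold <- function(cases, split, fold, net = net_config(),
                       pre = pre_config(), config = train_config()) {
  stopifnot(inherits(split, "fold_assignment"))
  if (!fold %in% unique(split$fold)) stop("fold not present in split")
  vi <- which(split$fold == fold)
  fit <- mt_fit(cases[-vi], cases[vi], net = net, pre = pre,
                config = config)
  fit$fold <- fold
  fit
}

#' Stratified k-fold cross-validation
#'
#' Trains one model per fold and pools the out-of-fold predictions, so each
#' case is predicted exactly once by a model that never saw it; cohort
#' metrics are computed on the pooled predictions.
#'
#' @param cases list of phantom cases.
#' @param k number of folds.
#' @param net,pre,config see [mt_fit()].
#' @return object of class `mt_cv`: per-fold `fits`, `split`, and `pooled`
#'   data frame (stage probabilities, predicted stage, DSC/ASD per case).
#' @export
run_cv <- function(cases, k = 3L, net = net_config(), pre = pre_config(),
                   config = train_config()) {
  labels <- vapply(cases, `[[`, integer(1), "stage")
  split <- stratified_kfold(labels, k, seed = config$seed)
  fits <- vector("list", k)
  rows <- list()
  for (f in seq_len(k) - 1L) {
    cfg_f <- config
    fits[[f + 1L]] <- train_fold(cases, split, f, net, pre, cfg_f)
    vi <- which(split$fold == f)
    for (ci in vi) {
      pr <- predict(fits[[f + 1L]], cases[[ci]])
      rows[[length(rows) + 1L]] <- data.frame(
        case_id = cases[[ci]]$case_id, fold = f,
        stage = cases[[ci]]$stage,
        p1 = pr$stage_probs[1], p2 = pr$stage_probs[2],
        p3 = pr$stage_probs[3], p4 = pr$stage_probs[4],
        pred_stage = pr$stage,
        dsc = as.numeric(dsc(pr$mask, pr$truth_mask)),
        asd_mm = suppressWarnings(asd(pr$mask, pr$truth_mask,
                                      fits[[f + 1L]]$pre$target_spacing)),
        stringsAsFactors = FALSE)
    }
  }
  structure(list(fits = fits, split = split,
                 pooled = do.call(rbind, rows), k = k),
            class = "mt_cv")
}

#' @export
print.mt_cv <- function(x, ...) {
  p <- x$pooled
  cat(sprintf("%d-fold cross-validation, %d pooled out-of-fold cases\n",
              x$k, nrow(p)))
  cat(sprintf("  pooled ACC %.3f | micro-AUC %.3f | median DSC %.3f\n",
              mean(p$pred_stage == p$stage),
              roc_auc_ovr(as.matrix(p[, c("p1", "p2", "p3", "p4")]),
                          p$stage, "micro"),
              stats::median(p$dsc)))
  invisible(x)
}

#' Cohort evaluation report from pooled predictions
#'
#' @param object an `mt_cv`.
#' @param level confidence level for the binomial intervals.
#' @param ... unused.
#' @return object of class `eval_report`: confusion table, ACC/SEN/SPE with
#'   Clopper-Pearson CI on accuracy, micro/macro one-vs-rest AUC, and the
#'   [score_cohort()]-style DSC/ASD summaries.
#' @export
summary.mt_cv <- function(object, level = 0.95, ...) {
  p <- object$pooled
  cm <- matrix(0L, 4L, 4L)
  for (i in seq_len(nrow(p)))
    cm[p$stage[i], p$pred_stage[i]] <- cm[p$stage[i], p$pred_stage[i]] + 1L
  cls <- acc_sen_spe(cm, level)
  probs <- as.matrix(p[, c("p1", "p2", "p3", "p4")])
  auc_mi <- roc_auc_ovr(probs, p$stage, "micro")
  auc_ma <- tryCatch(roc_auc_ovr(probs, p$stage, "macro"),
                     error = function(e) NA_real_)
  seg <- data.frame(
    metric = c("dsc", "asd_mm"),
    median = c(stats::median(p$dsc), stats::median(p$asd_mm, na.rm = TRUE)),
    iqr = c(diff(stats::quantile(p$dsc, c(.25, .75), names = FALSE)),
            diff(stats::quantile(p$asd_mm, c(.25, .75), na.rm = TRUE,
                                 names = FALSE))))
  structure(list(confusion = cm, classification = cls,
                 auc_micro = auc_mi, auc_macro = auc_ma,
                 segmentation = seg, n = nrow(p)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Cohort report, n = %d\n", x$n))
  ci <- x$classification$acc_ci
  cat(sprintf("  ACC %.2f (%d of %d; %.0f%% CI: %.2f, %.2f)\n",
              x$classification$acc, ci$k, ci$n, 100 * ci$level,
              ci$lower, ci$upper))
  cat(sprintf("  SEN %.2f | SPE %.2f | AUC micro %.2f | macro %s\n",
              x$classification$sen, x$classification$spe, x$auc_micro,
              ifelse(is.na(x$auc_macro), "NA",
                     sprintf("%.2f", x$auc_macro))))
  print(x$segmentation, row.names = FALSE)
  invisible(x)
}

#' Run an ablation protocol
#'
#' Trains under an ablated protocol on the same split, seed and epoch
#' budget as the corresponding full run, for paired comparison:
#' `"separate"` decouples the two tasks into sequential phases;
#' `"wo_ffa"` removes the fusion attention.
#'
#' @param mode `"full"`, `"separate"` or `"wo_ffa"`.
#' @param cases list of phantom cases.
#' @param net,pre,config see [mt_fit()]; `config$mode` is overridden.
#' @param fold fold index trained (default 0 of a 3-fold split).
#' @return an `mt_fit`.
#' @export
run_ablation <- function(mode, cases, net = net_config(),
                         pre = pre_config(), config = train_config(),
                         fold = 0L) {
  config$mode <- match.arg(mode, c("full", "separate", "wo_ffa"))
  labels <- vapply(cases, `[[`, integer(1), "stage")
  split <- stratified_kfold(labels, 3L, seed = config$seed)
  train_fold(cases, split, fold, net, pre, config)
}

#' Multi-seed ablation study
#'
#' Repeats, for each seed, a 3-fold cross-validation of the full multi-task
#' model and of its two ablations (plain-concatenation fusion and two-phase
#' separate training) on a fresh synthetic cohort, with identical splits,
#' seeds and epoch budgets within a seed.  Pooled out-of-fold staging AUC
#' (micro-average one-vs-rest), accuracy and median DSC are recorded per
#' run.
#'
#' @param n cohort size per seed.
#' @param seeds integer vector of seeds (one cohort + model per seed).
#' @param modes protocols to compare.
#' @param epochs epoch budget per fold (identical across modes).
#' @param lr learning rate of the desk-scale runs.
#' @param k folds.
#' @param phantom a [phantom_config()].
#' @param net,pre network/preprocessing configuration.
#' @param quiet suppress per-run progress.
#' @return data frame with one row per (seed, mode): `median_dsc`,
#'   `auc_micro`, `acc`.
#' @export
run_ablation_study <- function(n = 100L, seeds = 1:5,
                               modes = c("full", "wo_ffa", "separate"),
                               epochs = 5L, lr = 3e-3, k = 3L,
                               phantom = phantom_config(),
                               net = net_config(), pre = pre_config(),
                               quiet = FALSE) {
  rows <- list()
  for (s in seeds) {
    co <- generate_cohort(phantom, n = n, seed = s)
    cases <- prep_cohort(co$cases, pre)
    for (mode in modes) {
      cfg <- train_config(max_epochs = epochs, lr = lr, seed = s,
                          mode = mode)
      cv <- suppressWarnings(run_cv(cases, k, net = net, pre = pre,
                                    config = cfg))
      p <- cv$pooled
      auc <- roc_auc_ovr(as.matrix(p[, c("p1", "p2", "p3", "p4")]),
                         p$stage, "micro")
      rows[[length(rows) + 1L]] <- data.frame(
        seed = s, mode = mode, n = nrow(p),
        median_dsc = stats::median(p$dsc), auc_micro = auc,
        acc = mean(p$pred_stage == p$stage))
      if (!quiet)
        message(sprintf("seed %d %-9s median DSC %.3f AUC %.3f ACC %.2f",
                        s, mode, stats::median(p$dsc), auc,
                        mean(p$pred_stage == p$stage)))
    }
  }
  do.call(rbind, rows)
}

# ---- prediction and checkpoints --------------------------------------------

#' Predict segmentation and stage for one case
#'
#' Preprocesses the case (volume-centre crop: no mask is assumed at
#' inference) and runs the full forward pass.
#'
#' @param object an `mt_fit`.
#' @param case a phantom case, [volume_record()], or 3D array.
#' @param spacing spacing when `case` is a bare array.
#' @param ... unused.
#' @return list: `prob_map`, thresholded `mask`, `stage_probs`, `stage`,
#'   and `truth_mask` (the identically-cropped reference, when available).
#' @export
predict.mt_fit <- function(object, case, spacing = NULL, ...) {
  if (inherits(case, "volume_record"))
    case <- list(image = case$data, mask = array(0L, dim(case$data)),
                 stage = NA_integer_, spacing = case$spacing)
  else if (is.array(case))
    case <- list(image = case, mask = array(0L, dim(case)),
                 stage = NA_integer_,
                 spacing = if (is.null(spacing)) c(1, 1, 1) else spacing)
  prep <- .prep_case(case, object$pre, use_centroid = FALSE)
  fw <- .mt_forward_nodes(NULL, object$model, prep$image)
  pm <- array(fw$seg$prob$value, dim(prep$image))
  probs <- as.numeric(fw$cls$probs$value)
  list(prob_map = pm, mask = array(as.integer(pm >= 0.5), dim(pm)),
       stage_probs = probs, stage = which.max(probs),
       truth_mask = prep$mask, input = prep$image)
}

#' Export a trained model as a checkpoint
#'
#' @param fit an `mt_fit` (or `mt_model`).
#' @param path optional path; when given, the checkpoint is saved with
#'   [saveRDS()].
#' @return checkpoint list with parameter values, configs and an
#'   architecture fingerprint.
#' @export
save_checkpoint <- function(fit, path = NULL) {
  model <- if (inherits(fit, "mt_fit")) fit$model else fit
  ck <- list(values = lapply(model$params, function(p) p$value),
             config = model$config, mode = model$mode,
             pre = if (inherits(fit, "mt_fit")) fit$pre else pre_config(),
             fingerprint = model$fingerprint)
  if (!is.null(path)) saveRDS(ck, path)
  invisible(ck)
}

#' Load a checkpoint
#'
#' @param path path written by [save_checkpoint()].
#' @return the checkpoint list, fingerprint-verified.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$fingerprint, .fingerprint(ck$config)))
    stop("checkpoint fingerprint does not match its configuration")
  ck
}

#' Predict from a checkpoint
#'
#' Rebuilds the model from a checkpoint (verifying the architecture
#' fingerprint) and predicts one volume.
#'
#' @param checkpoint a [save_checkpoint()] list.
#' @param volume 3D array or [volume_record()].
#' @param spacing spacing when `volume` is a bare array.
#' @return as [predict.mt_fit()].
#' @export
predict_case <- function(checkpoint, volume, spacing = NULL) {
  if (!identical(checkpoint$fingerprint, .fingerprint(checkpoint$config)))
    stop("checkpoint fingerprint does not match its configuration")
  model <- mt_model(checkpoint$config, seed = 1L, mode = checkpoint$mode)
  for (nm in names(checkpoint$values))
    model$params[[nm]]$value <- checkpoint$values[[nm]]
  fake_fit <- structure(list(model = model, pre = checkpoint$pre),
                        class = "mt_fit")
  predict(fake_fit, volume, spacing = spacing)
}
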