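# Trainer tests run on a small shared cohort with a 2-3 epoch budget so the
# whole file stays in the seconds-to-a-minute range.

test_that("training is deterministic for a fixed seed", {
  co <- tiny_cohort()
  cases <- prep_cohort(co$cases)
  cfg <- train_config(max_epochs = 2, lr = 3e-3, seed = 5)
  f1 <- suppressWarnings(mt_fit(cases[1:16], cases[17:24], config = cfg))
  f2 <- suppressWarnings(mt_fit(cases[1:16], cases[17:24], config = cfg))
  expect_equal(f1$history, f2$history)
  expect_identical(f1$model$params[["seg.e1.w"]]$value,
                   f2$model$params[["seg.e1.w"]]$value)
})

test_that("the run stops when the learning rate falls below its floor", {
  co <- tiny_cohort()
  cases <- prep_cohort(co$cases)
  cfg <- train_config(max_epochs = 10, lr = 2e-4, seed = 1,
                      sched_factor = 1e-3, sched_patience = 0L,
                      sched_min_delta = Inf)
  fit <- suppressWarnings(mt_fit(cases[1:16], cases[17:24], config = cfg))
  expect_equal(fit$stop_reason, "min_lr")
  expect_equal(nrow(fit$history), 2L)   # 2e-4 -> 2e-7 -> 2e-10 < 1e-9
  # the stop reason is implied by the logged learning-rate trace
  expect_true(all(fit$history$lr >= cfg$min_lr))
  cfg2 <- train_config(max_epochs = 2, lr = 3e-3, seed = 1)
  fit2 <- suppressWarnings(mt_fit(cases[1:16], cases[17:24], config = cfg2))
  expect_equal(fit2$stop_reason, "max_epochs")
})

test_that("separate training leaves segmentation weights bit-identical in phase 2", {
  co <- tiny_cohort()
  cases <- prep_cohort(co$cases)
  cfgA <- train_config(max_epochs = 2, lr = 3e-3, seed = 3,
                       mode = "separate")
  cfgB <- train_config(max_epochs = 1, lr = 3e-3, seed = 3,
                       mode = "separate")
  fitA <- suppressWarnings(mt_fit(cases[1:16], cases[17:24], config = cfgA))
  fitB <- suppressWarnings(mt_fit(cases[1:16], cases[17:24], config = cfgB))
  seg_names <- grep("^seg\\.", names(fitA$model$params), value = TRUE)
  for (nm in seg_names)
    expect_identical(fitA$model$params[[nm]]$value,
                     fitB$model$params[[nm]]$value)
  expect_equal(unique(fitA$history$phase), c("seg", "cls"))
})

test_that("removing the fusion attention shrinks the parameter count", {
  full <- mt_model(net_config(), seed = 1, mode = "full")
  woffa <- mt_model(net_config(), seed = 1, mode = "wo_ffa")
  n_par <- function(m) sum(vapply(m$params, function(p) length(p$value),
                                  numeric(1)))
  expect_lt(n_par(woffa), n_par(full))
})

test_that("cross-validation pools each case exactly once with balanced folds", {
  co <- tiny_cohort()
  cases <- prep_cohort(co$cases)
  cfg <- train_config(max_epochs = 1, lr = 3e-3, seed = 7)
  cv <- suppressWarnings(run_cv(cases, 3, config = cfg))
  expect_setequal(cv$pooled$case_id, co$manifest$case_id)
  expect_equal(nrow(cv$pooled), 24L)
  per <- cv$split$table
  expect_true(all(apply(per, 1, function(r) max(r) - min(r)) <= 1))
  rep <- summary(cv)
  expect_equal(rep$classification$acc,
               sum(diag(rep$confusion)) / sum(rep$confusion))
  expect_equal(sum(rep$confusion), 24L)
})

test_that("prediction is deterministic and checkpoints carry a fingerprint", {
  co <- tiny_cohort()
  cases <- prep_cohort(co$cases)
  cfg <- train_config(max_epochs = 1, lr = 3e-3, seed = 2)
  fit <- suppressWarnings(mt_fit(cases[1:16], cases[17:24], config = cfg))
  p1 <- predict(fit, co$cases[[20]])
  p2 <- predict(fit, co$cases[[20]])
  expect_identical(p1$prob_map, p2$prob_map)
  expect_identical(p1$stage_probs, p2$stage_probs)
  expect_equal(dim(p1$mask), fit$pre$crop_shape, ignore_attr = TRUE)
  expect_lt(abs(sum(p1$stage_probs) - 1), 1e-6)
  ck_path <- tempfile(fileext = ".rds")
  save_checkpoint(fit, ck_path)
  ck <- load_checkpoint(ck_path)
  p3 <- predict_case(ck, co$cases[[20]]$image, spacing = co$cases[[20]]$spacing)
  expect_equal(p3$stage_probs, p1$stage_probs, tolerance = 1e-12)
  ck$config$seg_base <- 8L                  # tamper with the architecture
  expect_error(predict_case(ck, co$cases[[20]]$image), "fingerprint")
  unlink(ck_path)
})

test_that("ablation runs share budgets and data orderings with the full run", {
  co <- tiny_cohort()
  cases <- prep_cohort(co$cases)
  cfg <- train_config(max_epochs = 2, lr = 3e-3, seed = 9)
  fits <- lapply(c("full", "wo_ffa", "separate"), function(mode)
    suppressWarnings(run_ablation(mode, cases, config = cfg)))
  epochs <- vapply(fits, function(f) nrow(f$history), integer(1))
  expect_true(all(epochs == epochs[1]))
  expect_equal(fits[[1]]$fold, 0L)
})

test_that("a short training run learns both tasks above chance", {
  co <- generate_cohort(phantom_config(), n = 60, seed = 77)
  cases <- prep_cohort(co$cases)
  labels <- vapply(cases, `[[`, integer(1), "stage")
  split <- stratified_kfold(labels, 3, seed = 77)
  cfg <- train_config(max_epochs = 12, lr = 3e-3, seed = 77)
  fit <- suppressWarnings(train_fold(cases, split, 0, config = cfg))
  h <- fit$history[nrow(fit$history), ]
  expect_gt(h$val_dsc, 0.4)
  expect_gt(h$val_acc, 0.25)
})

test_that("paired model comparison runs the full test battery", {
  co <- tiny_cohort()
  cases <- prep_cohort(co$cases)
  cfg1 <- train_config(max_epochs = 1, lr = 3e-3, seed = 7)
  cfg2 <- train_config(max_epochs = 1, lr = 3e-3, seed = 7, mode = "wo_ffa")
  cva <- suppressWarnings(run_cv(cases, 3, config = cfg1))
  cvb <- suppressWarnings(run_cv(cases, 3, config = cfg2))
  cmp <- suppressWarnings(compare_cv(cva, cvb))
  expect_s3_class(cmp$delong, "htest")
  expect_s3_class(cmp$mcnemar, "htest")
  expect_true(cmp$delong$p.value >= 0 && cmp$delong$p.value <= 1)
  # comparing a run with itself is a perfect tie
  self <- suppressWarnings(compare_cv(cva, cva))
  expect_equal(self$delong$p.value, 1)
  expect_equal(self$mcnemar$p.value, 1)
  expect_equal(self$wilcoxon_dsc$p.value, 1)
})
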