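test_that("resampling is an identity at the native spacing and preserves constants", {
  v <- volume_record(array(rnorm(8 * 12 * 10), c(8, 12, 10)), c(2, 1, 1))
  r <- resample_volume(v, c(2, 1, 1))
  expect_identical(r$data, v$data)
  cv <- volume_record(array(3.7, c(2, 64, 64)), c(6, 1, 1))
  r2 <- resample_volume(cv, c(6, 0.5, 0.5))
  expect_equal(dim(r2$data), c(2L, 128L, 128L))
  expect_true(all(abs(r2$data - 3.7) < 1e-9))
})

test_that("downsampling a linear ramp evaluates the ramp at the new coordinates", {
  ramp <- array(0, c(4, 40, 6))
  for (h in 1:40) ramp[, h, ] <- 2 + 0.5 * (h - 1)
  v <- volume_record(ramp, c(6, 1, 1))
  r <- resample_volume(v, c(6, 2, 2))
  expect_equal(dim(r$data)[2], 20L)
  # output index i (0-based) sits at input coordinate 2 * i
  expected <- 2 + 0.5 * (2 * (0:19))
  expect_equal(r$data[2, , 2], expected, tolerance = 1e-6)
})

test_that("resampling round-trips: constants exactly, smooth fields within 1e-3", {
  x <- array(0, c(6, 24, 24))
  for (d in 1:6) for (h in 1:24) for (w in 1:24)
    x[d, h, w] <- sin(h / 5) * cos(w / 6) + 0.1 * d
  v <- volume_record(x, c(6, 1, 1))
  fine <- resample_volume(v, c(6, 0.5, 0.5))
  back <- resample_volume(fine, c(6, 1, 1))
  rel <- max(abs(back$data - x)) / max(abs(x))
  expect_lt(rel, 1e-3)
  const <- volume_record(array(2, c(6, 24, 24)), c(6, 1, 1))
  cb <- resample_volume(resample_volume(const, c(6, 0.5, 0.5)), c(6, 1, 1))
  expect_equal(cb$data, const$data)
})

test_that("masks stay strictly binary through the full chain", {
  co <- tiny_cohort()
  cc <- co$cases[[1]]
  m <- resample_volume(cc$mask, c(6, 1, 1), mask = TRUE,
                       spacing = cc$spacing)
  m <- crop_or_pad(m, c(10, 24, 24))
  expect_true(all(m$data %in% c(0L, 1L)))
  expect_error(resample_volume(cc$mask, c(-1, 1, 1), spacing = cc$spacing),
               "positive")
})

test_that("z-normalisation matches its definition and rejects constants", {
  x <- array(rnorm(500, 5, 3), c(5, 10, 10))
  z <- znormalize(x)
  expect_lt(abs(mean(z)), 1e-6)
  expect_lt(abs(sqrt(mean((z - mean(z))^2)) - 1), 1e-6)
  expect_equal(znormalize(z), z, tolerance = 1e-6)
  two <- array(c(0, 2), c(2, 1, 1))
  expect_equal(as.numeric(znormalize(two)), c(-1, 1))   # population SD
  expect_error(znormalize(array(1, c(2, 2, 2))), "constant")
})

test_that("crop_or_pad crops centrally, pads symmetrically and round-trips", {
  x <- array(rnorm(12 * 16 * 16), c(12, 16, 16))
  expect_identical(crop_or_pad(x, c(12, 16, 16)), x)
  big <- array(seq_len(32 * 256 * 256) %% 97, c(32, 256, 256))
  cr <- crop_or_pad(big, c(21, 224, 224))
  expect_equal(dim(cr), c(21L, 224L, 224L))
  expect_equal(cr, big[6:26, 16:239, 16:239])   # central block retained
  small <- crop_or_pad(x, c(6, 8, 8))
  back <- crop_or_pad(small, c(12, 16, 16))
  expect_equal(back[4:9, 5:12, 5:12], x[4:9, 4:11, 4:11])
  expect_true(all(back[1:3, , ] == 0))
})

test_that("stratified folds balance every stage to within one case", {
  labels <- rep(1:4, each = 3)
  f <- stratified_kfold(labels, k = 3, seed = 1)
  tab <- table(labels, f$fold)
  expect_true(all(tab == 1))
  # cohort with the clinical stage imbalance
  lab320 <- rep(1:4, times = c(26, 140, 87, 67))
  f3 <- stratified_kfold(lab320, k = 3, seed = 2)
  sizes <- as.integer(table(f3$fold))
  expect_equal(sum(sizes), 320L)
  expect_lte(max(sizes) - min(sizes), 1L)
  per <- table(lab320, f3$fold)
  expect_true(all(apply(per, 1, function(r) max(r) - min(r)) <= 1))
  expect_identical(stratified_kfold(lab320, 3, seed = 2)$fold, f3$fold)
  expect_error(stratified_kfold(1:3, k = 5, seed = 1), "split error")
})

test_that("fold proportions track the cohort within 1/min-class-size", {
  set.seed(3)
  labels <- sample(1:4, 90, TRUE, prob = c(.1, .4, .3, .2))
  f <- stratified_kfold(labels, 3, seed = 9)
  coh_prop <- prop.table(table(labels))
  for (k in 0:2) {
    fp <- prop.table(table(factor(labels[f$fold == k], levels = 1:4)))
    expect_true(all(abs(fp - coh_prop) <= 1 / min(table(labels)) + 1e-9))
  }
})
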