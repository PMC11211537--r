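test_that("Dice coefficient matches its formula and conventions", {
  a <- array(0L, c(3, 4, 4)); g <- a
  a[1, 1:2, 1:2] <- 1L; g[1, 1:2, 1:2] <- 1L
  expect_equal(as.numeric(dsc(a, g)), 1)
  g2 <- array(0L, dim(a)); g2[3, 3:4, 3:4] <- 1L
  expect_equal(as.numeric(dsc(a, g2)), 0)
  # |A| = |G| = 4, |A n G| = 2 -> 0.5
  a3 <- array(0L, dim(a)); a3[1, 1, 1:4] <- 1L
  g3 <- array(0L, dim(a)); g3[1, 1, 3:4] <- 1L; g3[1, 2, 1:2] <- 1L
  expect_equal(as.numeric(dsc(a3, g3)), 0.5)
  expect_equal(as.numeric(dsc(array(0L, dim(a)), array(0L, dim(a)))), 1)
  expect_equal(as.numeric(dsc(a, array(0L, dim(a)))), 0)
  expect_error(dsc(a, array(0L, c(3, 4, 5))), "mismatch")
  set.seed(1)
  for (i in 1:20) {
    x <- array(rbinom(48, 1, .4), c(3, 4, 4))
    y <- array(rbinom(48, 1, .4), c(3, 4, 4))
    expect_equal(as.numeric(dsc(x, y)), as.numeric(dsc(y, x)))
  }
})

test_that("surface distance respects anisotropic spacing", {
  m <- array(0L, c(4, 6, 6)); m[2, 3, 3] <- 1L
  expect_equal(asd(m, m, c(6, 0.5, 0.5)), 0)
  m2 <- array(0L, c(4, 6, 6)); m2[2, 4, 3] <- 1L     # one row over
  expect_equal(asd(m, m2, c(6, 0.5, 0.5)), 0.5)
  m3 <- array(0L, c(4, 6, 6)); m3[3, 3, 3] <- 1L     # one slice over
  expect_equal(asd(m, m3, c(6, 0.5, 0.5)), 6)
  expect_warning(v <- asd(m, array(0L, dim(m)), c(1, 1, 1)), "undefined")
  expect_true(is.na(v))
})

test_that("surface distance equals all-pairs brute force on random masks", {
  set.seed(7)
  sp <- c(3, 0.7, 1.2)
  for (i in 1:40) {
    a <- array(rbinom(9 * 9 * 5, 1, .3), c(9, 9, 5))
    g <- array(rbinom(9 * 9 * 5, 1, .3), c(9, 9, 5))
    if (sum(a) == 0 || sum(g) == 0) next
    expect_equal(asd(a, g, sp), asd_brute(a, g, sp), tolerance = 1e-9)
  }
})

test_that("eroding a mask degrades Dice and inflates surface distance", {
  a <- build_atlas(c(12, 24, 24), c(2, 1, 1), seed = 1)
  g <- array(as.integer(a$rho < 0.75), a$shape)
  erode <- function(m) {
    interior <- m
    dims <- dim(m)
    for (ax in 1:3) {
      up <- m; dn <- m
      idx <- slice.index(m, ax)
      up[idx < dims[ax]] <- m[idx > 1]; up[idx == dims[ax]] <- 0L
      dn[idx > 1] <- m[idx < dims[ax]]; dn[idx == 1] <- 0L
      interior <- interior * up * dn
    }
    interior
  }
  cur <- g
  d_prev <- 1; a_prev <- 0
  for (k in 1:2) {
    cur <- erode(cur)
    d_now <- as.numeric(dsc(cur, g))
    a_now <- asd(cur, g, c(2, 1, 1))
    expect_lt(d_now, d_prev)
    expect_gt(a_now, a_prev)
    d_prev <- d_now; a_prev <- a_now
  }
})

test_that("cohort score summaries use interpolated quartiles and bootstrap CIs", {
  mk <- function(k) {
    truth <- array(0L, c(4, 6, 6)); truth[2, 2:3, 1:5] <- 1L  # 10 voxels
    pred <- array(0L, dim(truth))
    ti <- which(truth == 1L)
    pred[ti[seq_len(k)]] <- 1L                                # k overlap
    pred[which(truth == 0L)[seq_len(10 - k)]] <- 1L           # pad to 10
    list(pred = pred, truth = truth, spacing = c(1, 1, 1))
  }
  cases <- lapply(c(6, 7, 8), mk)    # dsc = 0.6, 0.7, 0.8
  sc <- score_cohort(cases, boot = 500, seed = 1)
  drow <- sc$summary[sc$summary$metric == "dsc", ]
  expect_equal(drow$median, 0.7)
  expect_equal(drow$iqr, 0.1, tolerance = 1e-9)
  same <- score_cohort(cases[c(1, 1, 1)], boot = 500, seed = 1)
  srow <- same$summary[same$summary$metric == "dsc", ]
  expect_equal(srow$iqr, 0)
  expect_equal(srow$ci_lo, srow$ci_hi)
  expect_equal(srow$ci_lo, 0.6)
})

test_that("the bootstrap CI of the median covers the truth", {
  set.seed(11)
  hits <- 0
  trials <- 400
  for (i in seq_len(trials)) {
    x <- rnorm(50, 0.7, 0.1)
    bm <- matrix(sample(x, 1000 * 50, replace = TRUE), nrow = 1000)
    meds <- apply(bm, 1, median)
    ci <- quantile(meds, c(0.025, 0.975))
    if (ci[1] <= 0.7 && 0.7 <= ci[2]) hits <- hits + 1
  }
  expect_gte(hits / trials, 0.93)
})
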