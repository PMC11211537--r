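test_that("segmentation forward honours its shape and range contracts", {
  m <- mt_model(net_config(), seed = 4)
  vol <- array(rnorm(10 * 24 * 24), c(10, 24, 24))
  s <- seg_forward(vol, m)
  expect_equal(dim(s$prob_map), dim(vol))
  expect_true(all(s$prob_map > 0 & s$prob_map < 1))
  # taps live on the two deepest encoder grids and the first decoder grid
  expect_equal(dim(s$tap_e7)[2:4], m$config$seg_grids[[7]])
  expect_equal(dim(s$tap_e8)[2:4], m$config$seg_grids[[8]])
  expect_equal(dim(s$tap_d1)[2:4], m$config$seg_grids[[9]])
  expect_error(net_config(input_shape = c(10, 25, 24)), "row axis")
})

test_that("a zeroed final layer yields probability one half everywhere", {
  m <- mt_model(net_config(), seed = 4)
  m$params[["seg.out.w"]]$value[] <- 0
  m$params[["seg.out.b"]]$value[] <- 0
  s <- seg_forward(array(rnorm(10 * 24 * 24), c(10, 24, 24)), m)
  expect_true(all(s$prob_map == 0.5))
})

test_that("mask gating is an elementwise product", {
  v <- array(rnorm(4 * 5 * 6), c(4, 5, 6))
  expect_identical(mask_apply(v, array(1, dim(v))), v)
  expect_true(all(mask_apply(v, array(0, dim(v))) == 0))
  b <- array(rbinom(120, 1, .5), dim(v))
  mv <- mask_apply(v, b)
  expect_equal(mv[b == 1], v[b == 1])
  expect_true(all(mv[b == 0] == 0))
  expect_error(mask_apply(v, array(1, c(4, 5, 7))), "shapes differ")
})

test_that("backbone reaches the configured grid with or without attention", {
  cfg <- net_config()
  m <- mt_model(cfg, seed = 2)
  x <- array(rnorm(prod(cfg$input_shape)), cfg$input_shape)
  f <- backbone_forward(x, m)
  expect_equal(dim(f)[2:4], cfg$bb_grid)
  m2 <- mt_model(net_config(bb_attention = FALSE), seed = 2)
  f2 <- backbone_forward(x, m2)
  expect_equal(dim(f2), dim(f))   # drop-in conv fallback, same shapes
})

test_that("self-attention matches the two-loop oracle and normalises", {
  set.seed(8)
  N <- 3; C <- 8; heads <- 4
  x <- matrix(rnorm(N * C), N, C)
  pos <- matrix(rnorm(N * C, 0, 0.5), N, C)
  w <- list(wq = matrix(rnorm(C * C, 0, .4), C, C),
            wk = matrix(rnorm(C * C, 0, .4), C, C),
            wv = matrix(rnorm(C * C, 0, .4), C, C),
            wo = matrix(rnorm(C * C, 0, .4), C, C))
  r <- mhsa(x, pos, heads, w, return_weights = TRUE)
  expect_lt(max(abs(r$out - mhsa_oracle(x, pos, heads, w$wq, w$wk, w$wv,
                                        w$wo))), 1e-6)
  for (a in r$weights)
    expect_true(all(abs(rowSums(a) - 1) < 1e-6))
  expect_error(mhsa(x, pos, heads = 3), "divisible")
})

test_that("degenerate attention reduces to head-wise averages", {
  set.seed(9)
  N <- 5; C <- 8; heads <- 4; dh <- 2
  v <- matrix(rnorm(N * C), N, C)
  # q == 0 -> uniform weights -> each head returns its slice's column mean
  w <- list(wq = matrix(0, C, C), wk = diag(C), wv = diag(C), wo = diag(C))
  out <- mhsa(v, 0, heads, w)
  for (h in 1:heads) {
    cols <- ((h - 1) * dh + 1):(h * dh)
    expect_equal(out[1, cols], colMeans(v[, cols]), tolerance = 1e-9)
  }
  # a single position attends only to itself: output = wo mix of v
  one <- mhsa(v[1, , drop = FALSE], 0, heads)
  expect_equal(as.numeric(one), as.numeric(v[1, ]), tolerance = 1e-9)
})

test_that("attention without positions is permutation-equivariant", {
  set.seed(10)
  x <- matrix(rnorm(8 * 8), 8, 8)
  w <- list(wq = matrix(rnorm(64, 0, .3), 8), wk = matrix(rnorm(64, 0, .3), 8),
            wv = matrix(rnorm(64, 0, .3), 8), wo = matrix(rnorm(64, 0, .3), 8))
  perm <- sample(8)
  expect_equal(mhsa(x[perm, ], 0, 4, w), mhsa(x, 0, 4, w)[perm, ],
               tolerance = 1e-10)
})

test_that("feature fusion lands on the backbone grid in both fusion modes", {
  cfg <- net_config()
  m <- mt_model(cfg, seed = 6)
  vol <- array(rnorm(prod(cfg$input_shape)), cfg$input_shape)
  s <- seg_forward(vol, m)
  bb <- backbone_forward(mask_apply(vol, s$prob_map), m)
  fused <- ffa_fuse(s$tap_e7, s$tap_e8, s$tap_d1, bb, m)
  expect_equal(dim(fused)[2:4], cfg$bb_grid)
  expect_true(all(is.finite(fused)))
  m2 <- mt_model(cfg, seed = 6, mode = "wo_ffa")
  fused2 <- ffa_fuse(s$tap_e7, s$tap_e8, s$tap_d1, bb, m2)
  expect_equal(dim(fused2), dim(fused))
  # zeroed taps project to zero channels under plain concatenation
  z <- array(0, dim(s$tap_e7))
  m2$params[["ffa.t1.b"]]$value[] <- 0
  m2$params[["ffa.t2.b"]]$value[] <- 0
  m2$params[["ffa.t3.b"]]$value[] <- 0
  fz <- ffa_fuse(z, z, z, bb, m2)
  expect_true(all(fz[seq_len(3 * cfg$ffa_proj), , , ] == 0))
  expect_equal(fz[-seq_len(3 * cfg$ffa_proj), , , ], bb,
               ignore_attr = TRUE)
})

test_that("the classifier is a softmax head over pooled features", {
  cfg <- net_config()
  m <- mt_model(cfg, seed = 3)
  fused <- array(rnorm(56 * prod(cfg$bb_grid)), c(56, cfg$bb_grid))
  r <- classify_stage(fused, m)
  expect_length(r$probs, 4)
  expect_lt(abs(sum(r$probs) - 1), 1e-6)
  expect_equal(which.max(r$probs), which.max(r$logits))
  m$params[["cls.w"]]$value[] <- 0
  m$params[["cls.b"]]$value[] <- 0
  r0 <- classify_stage(array(0, dim(fused)), m)
  expect_equal(r0$probs, rep(0.25, 4))
})

test_that("analytic gradients match finite differences through the whole model", {
  env <- asNamespace("gtvstage")
  cfg <- net_config(cross_clip = 0)   # raw differentiable path
  m <- mt_model(cfg, seed = 5)
  set.seed(5)
  co <- tiny_cohort()
  preps <- lapply(co$cases[1:4], env$.prep_case, pre = pre_config(), TRUE)
  sw <- list(s_seg = env$ag_param(0), s_cls = env$ag_param(0))
  tc <- train_config()
  batch_loss <- function() {
    tot <- 0
    for (p in preps) {
      l <- env$.case_loss(NULL, m, p, sw, "joint", tc, training = FALSE)
      tot <- tot + l$total$value
    }
    tot
  }
  tape_loss <- function() {
    for (p in preps) {
      tape <- env$ag_tape()
      l <- env$.case_loss(tape, m, p, sw, "joint", tc, training = FALSE)
      env$ag_backward(tape, l$total)
    }
  }
  tape_loss()
  probes <- list(c("seg.e2.w", 5L), c("cls.w", 3L), c("bb.stem.w", 11L),
                 c("ffa.att.wq", 17L), c("seg.out.w", 2L))
  f0 <- batch_loss()
  for (pr in probes) {
    nm <- pr[1]; i <- as.integer(pr[2])
    g_an <- m$params[[nm]]$grad[i]
    # central differences at two step sizes: a ReLU/max-pool kink within
    # one step of the nominal point invalidates that step size, so the
    # better of the two is the honest comparison
    rel <- vapply(c(1e-5, 1e-6), function(eps) {
      m$params[[nm]]$value[i] <- m$params[[nm]]$value[i] + eps
      f_plus <- batch_loss()
      m$params[[nm]]$value[i] <- m$params[[nm]]$value[i] - 2 * eps
      f_minus <- batch_loss()
      m$params[[nm]]$value[i] <- m$params[[nm]]$value[i] + eps
      g_fd <- (f_plus - f_minus) / (2 * eps)
      abs(g_an - g_fd) / max(abs(g_an), abs(g_fd), 1e-8)
    }, numeric(1))
    expect_lt(min(rel), 1e-3)
  }
  env$ag_zero_grad(m$params)
})
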