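# Network architectures.
#
# Three pieces, mirroring the multi-task design:
#   * a U-shaped 3D segmentation network (8 encoder / 7 decoder units) whose
#     sigmoid output gates the input of the staging branch,
#   * a 4-stage residual "bottleneck transformer" backbone whose final three
#     bottleneck blocks replace their spatial convolution with multi-head
#     self-attention (MHSA),
#   * a feature-fusion-aware (FFA) module that projects the three
#     bottom-of-U segmentation feature taps onto the backbone grid,
#     concatenates them with the backbone features and mixes them with MHSA
#     before a global-average-pool + softmax classifier.
#
# All forward passes are expressed through the autodiff tape in autograd.R,
# so the whole model is differentiable end to end, including the
# mask-multiply gating between the two tasks.

#' Network configuration
#'
#' Builds and validates the architecture hyper-parameters for the multi-task
#' network.  Defaults are the "desk-scale" configuration: a tiny network
#' sized for CPU training on synthetic phantoms (input grid 10 x 24 x 24
#' after preprocessing).  A full-scale configuration for 21 x 224 x 224
#' clinical grids can be expressed through the same fields.
#'
#' @param input_shape integer(3), (slices, rows, columns) grid of the
#'   preprocessed input volume.
#' @param seg_base base channel width of the first encoder unit; widths
#'   double after every downsampling step, capped at `seg_cap`.
#' @param seg_cap maximum encoder/decoder channel width.
#' @param seg_pool list of 8 integer triples, per-encoder-unit pooling
#'   factors (1 or 2 per axis); in-plane pooling is max, slice pooling is
#'   average.
#' @param heads number of self-attention heads (must divide the attention
#'   channel widths).
#' @param bb_base,bb_cap backbone stage widths (base width, doubling per
#'   stage, capped).
#' @param bb_stem_pool pooling factors of the backbone stem.
#' @param bb_stage_pool list of 4 integer triples, pooling at each stage
#'   entry.
#' @param bb_blocks integer(4), number of bottleneck blocks per stage; the
#'   blocks of stage 4 use MHSA in place of their 3x3x3 convolution.
#' @param bb_attention logical; `FALSE` swaps the stage-4 MHSA back to a
#'   convolution (drop-in fallback, identical shapes).
#' @param ffa_proj channels each segmentation tap is projected to (1x1x1
#'   convolution) before fusion.
#' @param light_top if `TRUE` the finest-resolution decoder unit uses a
#'   pointwise (1x1x1) convolution instead of 3x3x3, trimming the cost of
#'   the most expensive layer at desk scale.
#' @param cross_clip maximum global norm of the staging-loss gradient
#'   flowing back into the segmentation network through each task
#'   interface (the soft mask gate and the three feature taps); 0 disables
#'   the bound.  Forward computation is unaffected.
#' @param dropout dropout rate applied to the pooled classifier features at
#'   training time.
#' @return an object of class `net_config`.
#' @export
net_config <- function(input_shape = c(10L, 24L, 24L),
                       seg_base = 4L, seg_cap = 24L,
                       seg_pool = list(c(1, 2, 2), c(2, 2, 2), c(1, 2, 2),
                                       c(1, 1, 1), c(1, 1, 1), c(1, 1, 1),
                                       c(1, 1, 1), c(1, 1, 1)),
                       heads = 4L,
                       bb_base = 8L, bb_cap = 32L,
                       bb_stem_pool = c(1, 2, 2),
                       bb_stage_pool = list(c(1, 1, 1), c(2, 2, 2),
                                            c(1, 2, 2), c(1, 1, 1)),
                       bb_blocks = c(1L, 1L, 1L, 3L),
                       bb_attention = TRUE,
                       ffa_proj = 8L,
                       light_top = TRUE,
                       cross_clip = 0.1,
                       dropout = 0) {
  input_shape <- as.integer(input_shape)
  stopifnot(length(input_shape) == 3L, all(input_shape >= 1L),
            length(seg_pool) == 8L, length(bb_stage_pool) == 4L,
            length(bb_blocks) == 4L, heads >= 1L, dropout >= 0, dropout < 1)
  for (f in c(seg_pool, list(bb_stem_pool), bb_stage_pool))
    if (!all(f %in% c(1, 2)))
      stop("pooling factors must be 1 or 2 per axis")
  cfg <- list(input_shape = input_shape, seg_base = as.integer(seg_base),
              seg_cap = as.integer(seg_cap), seg_pool = seg_pool,
              heads = as.integer(heads), bb_base = as.integer(bb_base),
              bb_cap = as.integer(bb_cap), bb_stem_pool = bb_stem_pool,
              bb_stage_pool = bb_stage_pool,
              bb_blocks = as.integer(bb_blocks),
              bb_attention = isTRUE(bb_attention),
              ffa_proj = as.integer(ffa_proj),
              light_top = isTRUE(light_top), cross_clip = cross_clip,
              dropout = dropout)
  # check the grid divides through every pooling step, naming the axis
  axn <- c("slice", "row", "column")
  g <- input_shape
  for (i in seq_len(8L)) {
    f <- seg_pool[[i]]
    for (a in 1:3)
      if (g[a] %% f[a] != 0L)
        stop(sprintf("encoder unit %d cannot pool the %s axis (size %d)",
                     i, axn[a], g[a]))
    g <- g %/% f
  }
  cfg$seg_grids <- .seg_grid_trace(cfg)
  gb <- input_shape %/% bb_stem_pool
  for (s in 1:4) {
    f <- bb_stage_pool[[s]]
    for (a in 1:3)
      if (gb[a] %% f[a] != 0L)
        stop(sprintf("backbone stage %d cannot pool the %s axis (size %d)",
                     s, axn[a], gb[a]))
    gb <- gb %/% f
  }
  cfg$bb_grid <- as.integer(gb)
  class(cfg) <- "net_config"
  cfg
}

# Grid after each encoder unit's pooling; row i = grid entering unit i+1.
.seg_grid_trace <- function(cfg) {
  g <- cfg$input_shape
  grids <- vector("list", 9L)
  grids[[1]] <- g
  for (i in seq_len(8L)) {
    g <- g %/% cfg$seg_pool[[i]]
    grids[[i + 1L]] <- as.integer(g)
  }
  grids
}

.enc_widths <- function(cfg) {
  pools <- vapply(cfg$seg_pool, function(f) any(f > 1), logical(1))
  w <- integer(8L)
  lev <- 0L
  for (i in seq_len(8L)) {
    w[i] <- min(cfg$seg_cap, cfg$seg_base * 2L^lev)
    if (pools[i]) lev <- lev + 1L
  }
  w
}

.bb_widths <- function(cfg)
  pmin(cfg$bb_cap, cfg$bb_base * 2L^(0:3))

# architecture fingerprint used to guard checkpoint/config mismatches
.fingerprint <- function(cfg)
  paste(c(cfg$input_shape, cfg$seg_base, cfg$seg_cap,
          unlist(cfg$seg_pool), cfg$heads, cfg$bb_base, cfg$bb_cap,
          cfg$bb_stem_pool, unlist(cfg$bb_stage_pool), cfg$bb_blocks,
          as.integer(cfg$bb_attention), cfg$ffa_proj,
          as.integer(cfg$light_top)), collapse = "-")

# ---- parameter construction -------------------------------------------------

.p_conv <- function(P, name, cin, cout, k, rnd = TRUE) {
  K <- cin * prod(k)
  sdv <- sqrt(2 / K)
  P[[paste0(name, ".w")]] <- ag_param(
    matrix(if (rnd) stats::rnorm(K * cout, 0, sdv) else 0, K, cout))
  P[[paste0(name, ".b")]] <- ag_param(numeric(cout))
  P
}

.p_norm <- function(P, name, ch) {
  P[[paste0(name, ".g")]] <- ag_param(rep(1, ch))
  P[[paste0(name, ".o")]] <- ag_param(numeric(ch))
  P
}

.p_mhsa <- function(P, name, ch, grid) {
  sdv <- sqrt(1 / ch)
  for (nm in c("wq", "wk", "wv", "wo"))
    P[[paste0(name, ".", nm)]] <- ag_param(
      matrix(stats::rnorm(ch * ch, 0, sdv), ch, ch))
  P[[paste0(name, ".pz")]] <- ag_param(
    matrix(stats::rnorm(grid[1] * ch, 0, 0.02), grid[1], ch))
  P[[paste0(name, ".py")]] <- ag_param(
    matrix(stats::rnorm(grid[2] * ch, 0, 0.02), grid[2], ch))
  P[[paste0(name, ".px")]] <- ag_param(
    matrix(stats::rnorm(grid[3] * ch, 0, 0.02), grid[3], ch))
  P
}

# Build every trainable parameter of the model for a given config.
.init_params <- function(cfg, seed = 1L) {
  seed <- as.integer(seed)
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(seed)
  P <- list()
  ew <- .enc_widths(cfg)
  # encoder
  cin <- 1L
  for (i in seq_len(8L)) {
    P <- .p_conv(P, sprintf("seg.e%d", i), cin, ew[i], c(3, 3, 3))
    P <- .p_norm(P, sprintf("seg.e%dn", i), ew[i])
    cin <- ew[i]
  }
  # decoder: units at constant bottom grid, then one per upsampling step
  up_units <- which(vapply(cfg$seg_pool, function(f) any(f > 1), logical(1)))
  n_up <- length(up_units)
  n_flat <- 7L - n_up
  dw <- ew[8]
  for (i in seq_len(n_flat)) {
    P <- .p_conv(P, sprintf("seg.d%d", i), dw, ew[8], c(3, 3, 3))
    P <- .p_norm(P, sprintf("seg.d%dn", i), ew[8])
    dw <- ew[8]
  }
  skip_units <- rev(up_units)            # encoder units whose pre-pool
  for (j in seq_len(n_up)) {             # outputs are skip-joined
    i <- n_flat + j
    su <- skip_units[j]
    cin_d <- dw + ew[su]
    cout_d <- ew[su]
    k_d <- if (cfg$light_top && i == 7L) c(1, 1, 1) else c(3, 3, 3)
    P <- .p_conv(P, sprintf("seg.d%d", i), cin_d, cout_d, k_d)
    P <- .p_norm(P, sprintf("seg.d%dn", i), cout_d)
    dw <- cout_d
  }
  # final 1x1x1 projection to the probability map; the bias starts at the
  # logit of a small foreground prior so the initial map predicts mostly
  # background, the standard initialisation for rare-foreground focal loss
  P <- .p_conv(P, "seg.out", dw, 1L, c(1, 1, 1))
  P[["seg.out.b"]]$value[] <- -2.9
  # backbone
  bw <- .bb_widths(cfg)
  P <- .p_conv(P, "bb.stem", 1L, bw[1], c(3, 3, 3))
  P <- .p_norm(P, "bb.stemn", bw[1])
  g <- cfg$input_shape %/% cfg$bb_stem_pool
  cin <- bw[1]
  for (s in 1:4) {
    g <- g %/% cfg$bb_stage_pool[[s]]
    for (bl in seq_len(cfg$bb_blocks[s])) {
      nm <- sprintf("bb.s%db%d", s, bl)
      mid <- max(1L, bw[s] %/% 4L)
      P <- .p_conv(P, paste0(nm, ".r"), cin, mid, c(1, 1, 1))
      P <- .p_norm(P, paste0(nm, ".rn"), mid)
      if (s == 4L && cfg$bb_attention) {
        P <- .p_mhsa(P, paste0(nm, ".att"), mid, g)
      } else {
        P <- .p_conv(P, paste0(nm, ".m"), mid, mid, c(3, 3, 3))
      }
      P <- .p_norm(P, paste0(nm, ".mn"), mid)
      P <- .p_conv(P, paste0(nm, ".x"), mid, bw[s], c(1, 1, 1))
      P <- .p_norm(P, paste0(nm, ".xn"), bw[s])
      if (cin != bw[s])
        P <- .p_conv(P, paste0(nm, ".p"), cin, bw[s], c(1, 1, 1))
      cin <- bw[s]
    }
  }
  # FFA: tap widths are encoder 7, encoder 8 and first decoder outputs
  d1_w <- if (n_flat >= 1L) ew[8] else ew[skip_units[1L]]
  tap_src <- c(ew[7L], ew[8L], d1_w)
  for (i in 1:3)
    P <- .p_conv(P, sprintf("ffa.t%d", i), tap_src[i], cfg$ffa_proj,
                 c(1, 1, 1))
  fused_ch <- bw[4] + 3L * cfg$ffa_proj
  P <- .p_mhsa(P, "ffa.att", fused_ch, cfg$bb_grid)
  # classifier
  P[["cls.w"]] <- ag_param(matrix(stats::rnorm(fused_ch * 4L, 0,
                                               sqrt(2 / fused_ch)),
                                  fused_ch, 4L))
  P[["cls.b"]] <- ag_param(numeric(4L))
  attr(P, "fused_ch") <- fused_ch
  P
}

#' Construct a multi-task model
#'
#' Creates the parameter set of the joint segmentation + staging network.
#'
#' @param config a [net_config()] object.
#' @param seed integer seed for weight initialisation.
#' @param mode `"full"` (joint training with FFA attention), `"wo_ffa"`
#'   (fusion by plain concatenation, no attention) or `"separate"`
#'   (two-phase training; architecture identical to `"full"`).
#' @return an object of class `mt_model`.
#' @export
mt_model <- function(config = net_config(), seed = 1L,
                     mode = c("full", "separate", "wo_ffa")) {
  mode <- match.arg(mode)
  params <- .init_params(config, seed)
  if (mode == "wo_ffa") {
    drop <- grep("^ffa\\.att\\.", names(params))
    if (length(drop)) params <- params[-drop]
  }
  structure(list(config = config, params = params, mode = mode,
                 fingerprint = .fingerprint(config), seed = seed),
            class = "mt_model")
}

#' @export
print.mt_model <- function(x, ...) {
  np <- sum(vapply(x$params, function(p) length(p$value), numeric(1)))
  cat("Multi-task GTV segmentation + T-staging network\n")
  cat(sprintf("  mode: %s | input grid: %s | parameters: %d\n",
              x$mode, paste(x$config$input_shape, collapse = "x"), np))
  invisible(x)
}

# ---- forward passes ---------------------------------------------------------

.conv_in_relu <- function(tape, x, P, name, k = c(3, 3, 3)) {
  ag_conv_in_relu(tape, x, P[[paste0(name, ".w")]],
                  P[[paste0(name, ".b")]], P[[paste0(name, "n.g")]],
                  P[[paste0(name, "n.o")]], as.integer(k))
}

# Mixed pooling step: max over in-plane factors, average over slices.
.pool_step <- function(tape, x, f) {
  if (f[2] > 1 || f[3] > 1)
    x <- ag_pool(tape, x, c(1L, f[2], f[3]), "max")
  if (f[1] > 1)
    x <- ag_pool(tape, x, c(f[1], 1L, 1L), "avg")
  x
}

# Segmentation network forward; returns nodes.
.seg_forward_nodes <- function(tape, x, P, cfg) {
  enc <- vector("list", 8L)
  h <- x
  for (i in seq_len(8L)) {
    h <- .conv_in_relu(tape, h, P, sprintf("seg.e%d", i))
    enc[[i]] <- h
    h <- .pool_step(tape, h, cfg$seg_pool[[i]])
  }
  up_units <- which(vapply(cfg$seg_pool, function(f) any(f > 1), logical(1)))
  n_up <- length(up_units)
  n_flat <- 7L - n_up
  dec1 <- NULL
  for (i in seq_len(n_flat)) {
    h <- .conv_in_relu(tape, h, P, sprintf("seg.d%d", i))
    if (i == 1L) dec1 <- h
  }
  skip_units <- rev(up_units)
  for (j in seq_len(n_up)) {
    i <- n_flat + j
    h <- ag_upsample(tape, h, cfg$seg_pool[[skip_units[j]]])
    h <- ag_concat_ch(tape, list(h, enc[[skip_units[j]]]))
    k_d <- if (cfg$light_top && i == 7L) c(1, 1, 1) else c(3, 3, 3)
    h <- .conv_in_relu(tape, h, P, sprintf("seg.d%d", i), k = k_d)
    if (i == 1L) dec1 <- h
  }
  logits <- ag_conv3d(tape, h, P[["seg.out.w"]], P[["seg.out.b"]],
                      c(1L, 1L, 1L))
  prob <- ag_sigmoid(tape, logits)
  list(prob = prob, tap_e7 = enc[[7L]], tap_e8 = enc[[8L]], tap_d1 = dec1)
}

# position index vectors for a (D,H,W) grid flattened d-fastest
.grid_index <- function(grid) {
  n <- seq_len(prod(grid)) - 1L
  list(z = (n %% grid[1]) + 1L,
       y = ((n %/% grid[1]) %% grid[2]) + 1L,
       x = (n %/% (grid[1] * grid[2])) + 1L)
}

# Multi-head self-attention over a sequence node (N x C), with factorised
# per-axis position encodings gathered for the grid.  Per head:
#   logits = (q k' + q pos') / sqrt(dh),  weights = softmax(logits),
#   z = weights v;  heads concatenated then linearly mixed.
.mhsa_nodes <- function(tape, xseq, P, name, grid, heads,
                        return_weights = FALSE) {
  C <- ncol(xseq$value)
  stopifnot(C %% heads == 0L)
  dh <- C %/% heads
  q <- ag_matmul(tape, xseq, P[[paste0(name, ".wq")]])
  k <- ag_matmul(tape, xseq, P[[paste0(name, ".wk")]])
  v <- ag_matmul(tape, xseq, P[[paste0(name, ".wv")]])
  gi <- .grid_index(grid)
  pz <- ag_gather_rows(tape, P[[paste0(name, ".pz")]], gi$z)
  py <- ag_gather_rows(tape, P[[paste0(name, ".py")]], gi$y)
  px <- ag_gather_rows(tape, P[[paste0(name, ".px")]], gi$x)
  pos <- ag_add(tape, ag_add(tape, pz, py), px)
  heads_out <- vector("list", heads)
  wts <- vector("list", heads)
  for (h in seq_len(heads)) {
    cols <- ((h - 1L) * dh + 1L):(h * dh)
    qh <- ag_slice_cols(tape, q, cols)
    kh <- ag_slice_cols(tape, k, cols)
    vh <- ag_slice_cols(tape, v, cols)
    ph <- ag_slice_cols(tape, pos, cols)
    lc <- ag_matmul_t(tape, qh, kh)
    lp <- ag_matmul_t(tape, qh, ph)
    lg <- ag_scale(tape, ag_add(tape, lc, lp), 1 / sqrt(dh))
    a <- ag_softmax_rows(tape, lg)
    wts[[h]] <- a
    heads_out[[h]] <- ag_matmul(tape, a, vh)
  }
  z <- ag_concat_cols(tape, heads_out)
  out <- ag_matmul(tape, z, P[[paste0(name, ".wo")]])
  if (return_weights) list(out = out, weights = wts) else out
}

# column slice / column concat for sequence matrices
ag_slice_cols <- function(tape, a, cols) {
  out <- ag_node(a$value[, cols, drop = FALSE])
  nc <- ncol(a$value)
  ag_record(tape, out, list(a), function(g) {
    d <- matrix(0, nrow(g), nc)
    d[, cols] <- g
    list(d)
  })
}

ag_concat_cols <- function(tape, nodes) {
  ncs <- vapply(nodes, function(n) ncol(n$value), integer(1))
  out <- ag_node(do.call(cbind, lapply(nodes, function(n) n$value)))
  ends <- cumsum(ncs); starts <- ends - ncs + 1L
  ag_record(tape, out, nodes, function(g)
    lapply(seq_along(nodes), function(i)
      g[, starts[i]:ends[i], drop = FALSE]))
}

# Bottleneck residual block; middle op is conv or MHSA.
.bb_block <- function(tape, x, P, name, grid, heads, attn) {
  h <- .conv_in_relu(tape, x, P, paste0(name, ".r"), k = c(1, 1, 1))
  if (attn) {
    s <- ag_to_seq(tape, h)
    s <- .mhsa_nodes(tape, s, P, paste0(name, ".att"), grid, heads)
    h <- ag_to_map(tape, s, grid)
  } else {
    h <- ag_conv3d(tape, h, P[[paste0(name, ".m.w")]],
                   P[[paste0(name, ".m.b")]], c(3L, 3L, 3L))
  }
  h <- ag_instnorm(tape, h, P[[paste0(name, ".mn.g")]],
                   P[[paste0(name, ".mn.o")]])
  h <- ag_relu(tape, h)
  h <- ag_conv3d(tape, h, P[[paste0(name, ".x.w")]],
                 P[[paste0(name, ".x.b")]], c(1L, 1L, 1L))
  h <- ag_instnorm(tape, h, P[[paste0(name, ".xn.g")]],
                   P[[paste0(name, ".xn.o")]])
  res <- x
  if (!is.null(P[[paste0(name, ".p.w")]]))
    res <- ag_conv3d(tape, x, P[[paste0(name, ".p.w")]],
                     P[[paste0(name, ".p.b")]], c(1L, 1L, 1L))
  ag_relu(tape, ag_add(tape, h, res))
}

.backbone_forward_nodes <- function(tape, x, P, cfg) {
  h <- .conv_in_relu(tape, x, P, "bb.stem")
  h <- .pool_step(tape, h, cfg$bb_stem_pool)
  g <- cfg$input_shape %/% cfg$bb_stem_pool
  for (s in 1:4) {
    f <- cfg$bb_stage_pool[[s]]
    if (any(f > 1)) h <- .pool_step(tape, h, f)
    g <- g %/% f
    for (bl in seq_len(cfg$bb_blocks[s]))
      h <- .bb_block(tape, h, P, sprintf("bb.s%db%d", s, bl), g,
                     cfg$heads, attn = (s == 4L && cfg$bb_attention))
  }
  h
}

.ffa_forward_nodes <- function(tape, taps, bb, P, cfg, use_attention = TRUE) {
  proj <- vector("list", 3L)
  for (i in 1:3) {
    p <- ag_conv3d(tape, taps[[i]], P[[sprintf("ffa.t%d.w", i)]],
                   P[[sprintf("ffa.t%d.b", i)]], c(1L, 1L, 1L))
    if (!identical(dim(p$value)[2:4], as.integer(cfg$bb_grid)))
      p <- ag_resize3(tape, p, cfg$bb_grid)
    proj[[i]] <- p
  }
  fused <- ag_concat_ch(tape, c(proj, list(bb)))
  if (use_attention) {
    s <- ag_to_seq(tape, fused)
    a <- .mhsa_nodes(tape, s, P, "ffa.att", cfg$bb_grid, cfg$heads)
    s <- ag_add(tape, s, a)          # residual connection around MHSA
    fused <- ag_to_map(tape, s, cfg$bb_grid)
  }
  fused
}

.classify_nodes <- function(tape, fused, P, dropout = 0, training = FALSE) {
  g <- ag_gap(tape, fused)
  if (training && dropout > 0) {
    keep <- (stats::runif(length(g$value)) >= dropout) / (1 - dropout)
    g <- ag_mul(tape, g, ag_const(matrix(keep, 1L)))
  }
  logits <- ag_bias_rows(tape, ag_matmul(tape, g, P[["cls.w"]]),
                         P[["cls.b"]])
  probs <- ag_softmax_rows(tape, logits)
  list(probs = probs, logits = logits)
}

# Full multi-task forward pass on one preprocessed volume (D,H,W array).
# Returns all intermediate nodes needed by the loss.
.mt_forward_nodes <- function(tape, model, vol, training = FALSE,
                              detach_seg = FALSE) {
  cfg <- model$config
  if (!identical(dim(vol), as.integer(cfg$input_shape)))
    stop(sprintf("input grid %s does not match configured %s",
                 paste(dim(vol), collapse = "x"),
                 paste(cfg$input_shape, collapse = "x")))
  x <- ag_const(array(vol, c(1L, dim(vol))))
  seg <- .seg_forward_nodes(tape, x, model$params, cfg)
  gate <- if (detach_seg) ag_const(seg$prob$value) else seg$prob
  taps <- list(seg$tap_e7, seg$tap_e8, seg$tap_d1)
  if (!detach_seg && cfg$cross_clip > 0) {
    gate <- ag_grad_clip(tape, gate, cfg$cross_clip)
    taps <- lapply(taps, ag_grad_clip, tape = tape,
                   max_norm = cfg$cross_clip)
  }
  masked <- ag_mul(tape, x, gate)
  bb <- .backbone_forward_nodes(tape, masked, model$params, cfg)
  fused <- .ffa_forward_nodes(tape, taps, bb, model$params, cfg,
                              use_attention = (model$mode != "wo_ffa"))
  cls <- .classify_nodes(tape, fused, model$params, cfg$dropout, training)
  list(seg = seg, masked = masked, backbone = bb, fused = fused, cls = cls)
}

# ---- exported forward-contract wrappers ------------------------------------

#' Segmentation network forward pass
#'
#' Runs the U-shaped 3D segmentation network on a preprocessed volume and
#' returns the voxelwise tumor-probability map together with the three
#' bottom-of-U feature taps (seventh encoder, final encoder, first decoder)
#' that feed the staging branch.
#'
#' @param volume 3D numeric array matching the configured input grid.
#' @param model an [mt_model()].
#' @return list with `prob_map` (same grid as the input, values in `[0,1]`)
#'   and feature arrays `tap_e7`, `tap_e8`, `tap_d1` (channel-first).
#' @export
seg_forward <- function(volume, model) {
  r <- .seg_forward_nodes(NULL, ag_const(array(volume, c(1L, dim(volume)))),
                          model$params, model$config)
  list(prob_map = array(r$prob$value, dim(volume)),
       tap_e7 = r$tap_e7$value, tap_e8 = r$tap_e8$value,
       tap_d1 = r$tap_d1$value)
}

#' Gate a volume by a segmentation probability map
#'
#' Elementwise product of the image and the (soft) segmentation map; the
#' result is the input of the T-stage prediction network.
#'
#' @param volume,prob_map arrays of identical shape.
#' @return array of the same shape.
#' @export
mask_apply <- function(volume, prob_map) {
  if (!identical(dim(volume), dim(prob_map)))
    stop("volume and prob_map shapes differ")
  volume * prob_map
}

#' Staging backbone forward pass
#'
#' Runs the 4-stage residual backbone (final-stage bottleneck blocks use
#' multi-head self-attention) on a masked volume.
#'
#' @param masked_volume 3D array, typically [mask_apply()] output.
#' @param model an [mt_model()].
#' @return channel-first feature array on the final backbone grid.
#' @export
backbone_forward <- function(masked_volume, model) {
  x <- ag_const(array(masked_volume, c(1L, dim(masked_volume))))
  .backbone_forward_nodes(NULL, x, model$params, model$config)$value
}

#' Multi-head self-attention on a feature sequence
#'
#' Stand-alone MHSA: per head, attention logits are the scaled sum of the
#' content term `q k'` and the position term `q pos'`; softmax over key
#' positions; head outputs are concatenated and linearly mixed.
#'
#' @param x numeric matrix, N positions x C channels.
#' @param pos numeric matrix N x C of position encodings (0 to disable).
#' @param heads number of heads; must divide C.
#' @param weights optional list with `wq`, `wk`, `wv`, `wo` (C x C
#'   matrices); identity by default.
#' @param return_weights if `TRUE`, also return each head's attention
#'   weight matrix.
#' @return N x C output matrix (or list with `out` and `weights`).
#' @export
mhsa <- function(x, pos = 0, heads = 4L, weights = NULL,
                 return_weights = FALSE) {
  C <- ncol(x)
  if (C %% heads != 0L) stop("channel count not divisible by heads")
  dh <- C %/% heads
  if (is.null(weights))
    weights <- list(wq = diag(C), wk = diag(C), wv = diag(C), wo = diag(C))
  if (length(pos) == 1L) pos <- matrix(pos, nrow(x), C)
  q <- x %*% weights$wq; k <- x %*% weights$wk; v <- x %*% weights$wv
  outs <- vector("list", heads); wts <- vector("list", heads)
  for (h in seq_len(heads)) {
    cols <- ((h - 1L) * dh + 1L):(h * dh)
    lg <- (q[, cols, drop = FALSE] %*% t(k[, cols, drop = FALSE]) +
           q[, cols, drop = FALSE] %*% t(pos[, cols, drop = FALSE])) /
          sqrt(dh)
    lg <- lg - apply(lg, 1L, max)
    a <- exp(lg); a <- a / rowSums(a)
    wts[[h]] <- a
    outs[[h]] <- a %*% v[, cols, drop = FALSE]
  }
  out <- do.call(cbind, outs) %*% weights$wo
  if (return_weights) list(out = out, weights = wts) else out
}

#' Feature-fusion-aware module
#'
#' Projects the three segmentation taps to a common width, resizes them to
#' the backbone grid (trilinear), concatenates them with the backbone
#' features along channels, and mixes the result with a residual MHSA block
#' (or returns the plain concatenation for the wo-FFA ablation).
#'
#' @param tap_e7,tap_e8,tap_d1 channel-first segmentation feature arrays.
#' @param backbone_feat channel-first backbone feature array.
#' @param model an [mt_model()].
#' @return fused channel-first feature array on the backbone grid.
#' @export
ffa_fuse <- function(tap_e7, tap_e8, tap_d1, backbone_feat, model) {
  taps <- list(ag_const(tap_e7), ag_const(tap_e8), ag_const(tap_d1))
  .ffa_forward_nodes(NULL, taps, ag_const(backbone_feat), model$params,
                     model$config,
                     use_attention = (model$mode != "wo_ffa"))$value
}

#' Stage classifier
#'
#' Global average pooling, affine map and softmax over the four T stages.
#'
#' @param fused channel-first feature array from [ffa_fuse()].
#' @param model an [mt_model()].
#' @return list with `probs` (length 4, sums to 1) and `logits` (length 4).
#' @export
classify_stage <- function(fused, model) {
  r <- .classify_nodes(NULL, ag_const(fused), model$params)
  list(probs = as.numeric(r$probs$value), logits = as.numeric(r$logits$value))
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restore_rng <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}
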