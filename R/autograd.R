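# Minimal reverse-mode automatic differentiation.
#
# A "node" is an environment holding $value (numeric array) and, after
# backward(), $grad.  Every differentiable operation appends one record to a
# tape: the output node, its input nodes, and a closure mapping the output
# gradient to input gradients.  backward() walks the tape in reverse and
# accumulates.  Parameters are long-lived nodes reused across tapes.

ag_tape <- function() {
  e <- new.env(parent = emptyenv())
  e$ops <- vector("list", 256L)
  e$n <- 0L
  e
}

ag_node <- function(value, requires_grad = TRUE) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$grad <- NULL
  e$requires_grad <- requires_grad
  class(e) <- "ag_node"
  e
}

ag_param <- function(value) ag_node(value, requires_grad = TRUE)
ag_const <- function(value) ag_node(value, requires_grad = FALSE)

ag_record <- function(tape, out, inputs, bwd) {
  if (!is.null(tape)) {
    tape$n <- tape$n + 1L
    if (tape$n > length(tape$ops))
      length(tape$ops) <- 2L * length(tape$ops)
    tape$ops[[tape$n]] <- list(out = out, inputs = inputs, bwd = bwd)
  }
  out
}

ag_accum <- function(node, g) {
  if (!isTRUE(node$requires_grad)) return(invisible(NULL))
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
  invisible(NULL)
}

# Backpropagate from a scalar loss node through every op on the tape.
ag_backward <- function(tape, loss) {
  loss$grad <- 1
  if (tape$n == 0L) return(invisible(NULL))
  for (i in seq(tape$n, 1L)) {
    op <- tape$ops[[i]]
    g <- op$out$grad
    if (is.null(g)) next
    gs <- op$bwd(g)
    for (j in seq_along(op$inputs)) {
      if (!is.null(gs[[j]])) ag_accum(op$inputs[[j]], gs[[j]])
    }
    # free intermediate gradients (parameters keep theirs)
    if (!isTRUE(attr(op$out, "keep_grad"))) op$out$grad <- NULL
  }
  invisible(NULL)
}

ag_zero_grad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# ---- elementwise and shape ops ---------------------------------------------

ag_add <- function(tape, a, b) {
  out <- ag_node(a$value + b$value)
  ag_record(tape, out, list(a, b), function(g) list(g, g))
}

ag_mul <- function(tape, a, b) {
  av <- a$value; bv <- b$value
  out <- ag_node(av * bv)
  ag_record(tape, out, list(a, b), function(g) list(g * bv, g * av))
}

ag_scale <- function(tape, a, k) {
  out <- ag_node(a$value * k)
  ag_record(tape, out, list(a), function(g) list(g * k))
}

# Identity forward; backward rescales the gradient so its global norm does
# not exceed `max_norm`.  Used at the seg->cls task interfaces, where the
# staging loss otherwise back-propagates gradients orders of magnitude
# larger than the segmentation loss's own.
ag_grad_clip <- function(tape, a, max_norm) {
  out <- ag_node(a$value)
  ag_record(tape, out, list(a), function(g) {
    n <- sqrt(sum(g * g))
    if (n > max_norm) g <- g * (max_norm / n)
    list(g)
  })
}

ag_relu <- function(tape, a) {
  keep <- a$value > 0
  out <- ag_node(a$value * keep)
  ag_record(tape, out, list(a), function(g) list(g * keep))
}

ag_sigmoid <- function(tape, a) {
  s <- 1 / (1 + exp(-a$value))
  out <- ag_node(s)
  ag_record(tape, out, list(a), function(g) list(g * s * (1 - s)))
}

# Concatenate (C,D,H,W) feature maps along the channel axis.
ag_concat_ch <- function(tape, nodes) {
  dims <- lapply(nodes, function(n) dim(n$value))
  ch <- vapply(dims, `[`, integer(1), 1L)
  sp <- dims[[1]][2:4]
  mats <- lapply(nodes, function(n) matrix(n$value, nrow = dim(n$value)[1]))
  out_v <- do.call(rbind, mats)
  out <- ag_node(array(out_v, c(sum(ch), sp)))
  ends <- cumsum(ch); starts <- ends - ch + 1L
  ag_record(tape, out, nodes, function(g) {
    gm <- matrix(g, nrow = sum(ch))
    lapply(seq_along(nodes), function(i)
      array(gm[starts[i]:ends[i], , drop = FALSE], c(ch[i], sp)))
  })
}

# (C,D,H,W) map -> N x C sequence matrix (N = spatial positions).
ag_to_seq <- function(tape, a) {
  dd <- dim(a$value)
  out <- ag_node(t(matrix(a$value, nrow = dd[1])))
  ag_record(tape, out, list(a), function(g) list(array(t(g), dd)))
}

ag_to_map <- function(tape, a, spatial) {
  out <- ag_node(array(t(a$value), c(ncol(a$value), spatial)))
  dd <- dim(a$value)
  ag_record(tape, out, list(a), function(g)
    list(t(matrix(g, nrow = dim(g)[1]))))
}

# ---- matrix ops -------------------------------------------------------------

ag_matmul <- function(tape, a, b) {
  av <- a$value; bv <- b$value
  out <- ag_node(av %*% bv)
  ag_record(tape, out, list(a, b), function(g)
    list(g %*% t(bv), t(av) %*% g))
}

ag_matmul_t <- function(tape, a, b) {   # a %*% t(b)
  av <- a$value; bv <- b$value
  out <- ag_node(av %*% t(bv))
  ag_record(tape, out, list(a, b), function(g)
    list(g %*% bv, t(g) %*% av))
}

# Row-wise bias add for an N x C matrix.
ag_bias_rows <- function(tape, a, b) {
  out <- ag_node(sweep(a$value, 2L, b$value, `+`))
  ag_record(tape, out, list(a, b), function(g) list(g, colSums(g)))
}

# Softmax over each row of a matrix.
ag_softmax_rows <- function(tape, a) {
  v <- a$value
  v <- v - apply(v, 1L, max)
  e <- exp(v)
  s <- e / rowSums(e)
  out <- ag_node(s)
  ag_record(tape, out, list(a), function(g) {
    dot <- rowSums(g * s)
    list(s * (g - dot))
  })
}

# Gather rows of an embedding matrix: out[i,] = emb[idx[i],].
ag_gather_rows <- function(tape, emb, idx) {
  ev <- emb$value
  out <- ag_node(ev[idx, , drop = FALSE])
  ag_record(tape, out, list(emb), function(g) {
    de <- matrix(0, nrow(ev), ncol(ev))
    for (i in seq_along(idx)) de[idx[i], ] <- de[idx[i], ] + g[i, ]
    list(de)
  })
}

# ---- compiled-kernel ops ----------------------------------------------------

ag_conv3d <- function(tape, x, w, b, ksz) {
  xv <- x$value
  if (all(ksz == 1L)) {
    out <- ag_node(cpp_conv1x1_fwd(xv, dim(xv), w$value, b$value))
    return(ag_record(tape, out, list(x, w, b), function(g) {
      gr <- cpp_conv1x1_bwd(xv, dim(xv), w$value, g)
      list(gr$dx, gr$dw, gr$db)
    }))
  }
  out <- ag_node(cpp_conv3d_fwd(xv, dim(xv), w$value, b$value, ksz))
  ag_record(tape, out, list(x, w, b), function(g) {
    gr <- cpp_conv3d_bwd(xv, dim(xv), w$value, g, ksz)
    list(gr$dx, gr$dw, gr$db)
  })
}

ag_pool <- function(tape, x, f, type = c("max", "avg")) {
  type <- match.arg(type)
  ti <- if (type == "max") 0L else 1L
  dims <- dim(x$value)
  r <- cpp_pool_fwd(x$value, dims, as.integer(f), ti)
  out <- ag_node(r$y)
  ag_record(tape, out, list(x), function(g)
    list(cpp_pool_bwd(g, dims, as.integer(f), ti, r$argmax)))
}

ag_upsample <- function(tape, x, f) {
  dims <- dim(x$value)
  out <- ag_node(cpp_upsample_fwd(x$value, dims, as.integer(f)))
  ag_record(tape, out, list(x), function(g)
    list(cpp_upsample_bwd(g, dims, as.integer(f))))
}

ag_resize3 <- function(tape, x, out_spatial) {
  dims <- dim(x$value)
  out <- ag_node(cpp_resize3_fwd(x$value, dims, as.integer(out_spatial)))
  ag_record(tape, out, list(x), function(g)
    list(cpp_resize3_bwd(g, dims, as.integer(out_spatial))))
}

# ---- normalisation, pooling heads, losses as primitive ops ------------------

# Fused conv3d -> instance norm -> ReLU, the standard layer block; one
# tape record instead of three.
ag_conv_in_relu <- function(tape, x, w, b, gain, nbias, ksz, eps = 1e-5) {
  xv <- x$value
  dd <- dim(xv)
  r <- cpp_cir_fwd(xv, dd, w$value, b$value, as.integer(ksz),
                   gain$value, nbias$value, eps)
  out <- ag_node(r$y)
  ag_record(tape, out, list(x, w, b, gain, nbias), function(g) {
    bb <- cpp_cir_bwd(g, xv, dd, w$value, as.integer(ksz), gain$value,
                      r$xhat, r$istd, r$keep)
    list(bb$dx, bb$dw, bb$db, bb$dgain, bb$dbias)
  })
}

# Per-channel instance normalisation with learnable gain/bias.
ag_instnorm <- function(tape, x, gain, bias, eps = 1e-5) {
  dd <- dim(x$value)
  r <- cpp_instnorm_fwd(x$value, dd, gain$value, bias$value, eps)
  out <- ag_node(r$y)
  ag_record(tape, out, list(x, gain, bias), function(g) {
    b <- cpp_instnorm_bwd(g, r$xhat, r$istd, gain$value, dd)
    list(b$dx, b$dgain, b$dbias)
  })
}

# Global average pool: (C,D,H,W) -> 1 x C row vector.
ag_gap <- function(tape, x) {
  dd <- dim(x$value)
  C <- dd[1]; N <- prod(dd[-1])
  out <- ag_node(matrix(rowMeans(matrix(x$value, nrow = C)), 1L, C))
  ag_record(tape, out, list(x), function(g)
    list(array(rep(as.numeric(g) / N, N), dd)))
}

# Soft Jaccard loss 1 - (|pred*truth|+eps)/(|pred|+|truth|-|pred*truth|+eps).
ag_jaccard_loss <- function(tape, pred, truth, eps = 1) {
  p <- pred$value; t0 <- truth
  i <- sum(p * t0)
  u <- sum(p) + sum(t0) - i
  out <- ag_node(1 - (i + eps) / (u + eps))
  ag_record(tape, out, list(pred), function(g) {
    # d/dp of -(i+eps)/(u+eps): quotient rule, du/dp = 1 - t, di/dp = t
    d <- -(t0 * (u + eps) - (i + eps) * (1 - t0)) / (u + eps)^2
    list(g * d)
  })
}

# Focal loss, mean over voxels of -alpha_t (1-p_t)^gamma log(p_t).
ag_focal_loss <- function(tape, pred, truth, gamma = 2, alpha = 0.75,
                          clip = 1e-7) {
  p <- pmin(pmax(pred$value, clip), 1 - clip)
  pt <- truth * p + (1 - truth) * (1 - p)        # truth-class probability
  at <- alpha * truth + (1 - alpha) * (1 - truth)
  n <- length(p)
  om <- 1 - pt
  out <- ag_node(sum(at * om^gamma * (-log(pt))) / n)
  inside <- (pred$value > clip & pred$value < 1 - clip)
  ag_record(tape, out, list(pred), function(g) {
    # d/dpt [-at (1-pt)^g log pt] = at [g (1-pt)^(g-1) log pt - (1-pt)^g/pt]
    dpt <- if (gamma == 0) at * (-1 / pt)
           else at * (gamma * om^(gamma - 1) * log(pt) - om^gamma / pt)
    dp <- (2 * truth - 1) * dpt / n              # dpt/dp = 2t - 1
    list(g * dp * inside)
  })
}

# Cross-entropy for a 1 x K probability row against an integer label.
ag_ce_loss <- function(tape, probs, label, clip = 1e-12) {
  p <- max(probs$value[1, label], clip)
  out <- ag_node(-log(p))
  ag_record(tape, out, list(probs), function(g) {
    d <- matrix(0, 1L, ncol(probs$value))
    d[1, label] <- -g / p
    list(d)
  })
}

# Homoscedastic-uncertainty combination:
#   total = exp(-s_seg) L_seg + s_seg + exp(-s_cls) L_cls + s_cls
ag_uncertainty_sum <- function(tape, l_seg, l_cls, s_seg, s_cls) {
  ws <- exp(-s_seg$value); wc <- exp(-s_cls$value)
  out <- ag_node(ws * l_seg$value + s_seg$value + wc * l_cls$value +
                 s_cls$value)
  ag_record(tape, out, list(l_seg, l_cls, s_seg, s_cls), function(g)
    list(g * ws, g * wc,
         g * (1 - ws * l_seg$value), g * (1 - wc * l_cls$value)))
}

# Fixed-weight combination total = w_seg L_seg + w_cls L_cls.
ag_weighted_sum <- function(tape, l_seg, l_cls, w_seg, w_cls) {
  out <- ag_node(w_seg * l_seg$value + w_cls * l_cls$value)
  ag_record(tape, out, list(l_seg, l_cls), function(g)
    list(g * w_seg, g * w_cls))
}
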