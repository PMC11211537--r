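# Independent oracles used across the suite: deliberately naive
# implementations kept separate from the package's own code paths.

# connected-component count of a binary 3D array, 6-neighbourhood flood fill
cc_count <- function(mask) {
  dims <- dim(mask)
  seen <- array(FALSE, dims)
  idx <- which(mask != 0)
  comps <- 0L
  D <- dims[1]; H <- dims[2]
  for (start in idx) {
    if (seen[start]) next
    comps <- comps + 1L
    stack <- start
    seen[start] <- TRUE
    while (length(stack)) {
      li <- stack[length(stack)]; stack <- stack[-length(stack)]
      d <- ((li - 1L) %% D) + 1L
      h <- (((li - 1L) %/% D) %% H) + 1L
      w <- ((li - 1L) %/% (D * H)) + 1L
      for (nb in c(if (d > 1) li - 1L, if (d < dims[1]) li + 1L,
                   if (h > 1) li - D, if (h < dims[2]) li + D,
                   if (w > 1) li - D * H, if (w < dims[3]) li + D * H)) {
        if (mask[nb] != 0 && !seen[nb]) {
          seen[nb] <- TRUE
          stack <- c(stack, nb)
        }
      }
    }
  }
  comps
}

# all-pairs brute-force average symmetric surface distance
asd_brute <- function(a, g, spacing) {
  surf <- function(m) {
    dims <- dim(m)
    out <- matrix(0, 0, 3)
    for (d in seq_len(dims[1])) for (h in seq_len(dims[2]))
      for (w in seq_len(dims[3])) {
        if (m[d, h, w] == 0) next
        nb_bg <- (d == 1 || m[d - 1, h, w] == 0) ||
                 (d == dims[1] || m[d + 1, h, w] == 0) ||
                 (h == 1 || m[d, h - 1, w] == 0) ||
                 (h == dims[2] || m[d, h + 1, w] == 0) ||
                 (w == 1 || m[d, h, w - 1] == 0) ||
                 (w == dims[3] || m[d, h, w + 1] == 0)
        if (nb_bg) out <- rbind(out, c(d, h, w))
      }
    out
  }
  sa <- surf(a); sg <- surf(g)
  dmin <- function(from, to) {
    vapply(seq_len(nrow(from)), function(i) {
      dd <- sweep(to, 2, from[i, ])
      min(sqrt(colSums((t(dd) * spacing)^2)))
    }, numeric(1))
  }
  (mean(dmin(sa, sg)) + mean(dmin(sg, sa))) / 2
}

# two-loop multi-head self-attention oracle:
# logits = (q k' + q pos') / sqrt(dh), softmax rows, z = w v;
# heads concatenated then mixed by wo.
mhsa_oracle <- function(x, pos, heads, wq, wk, wv, wo) {
  C <- ncol(x); N <- nrow(x); dh <- C / heads
  q <- x %*% wq; k <- x %*% wk; v <- x %*% wv
  out_heads <- NULL
  for (h in seq_len(heads)) {
    cols <- ((h - 1) * dh + 1):(h * dh)
    z <- matrix(0, N, dh)
    for (i in seq_len(N)) {
      lg <- numeric(N)
      for (j in seq_len(N))
        lg[j] <- (sum(q[i, cols] * k[j, cols]) +
                  sum(q[i, cols] * pos[j, cols])) / sqrt(dh)
      wgt <- exp(lg - max(lg)); wgt <- wgt / sum(wgt)
      for (j in seq_len(N)) z[i, ] <- z[i, ] + wgt[j] * v[j, cols]
    }
    out_heads <- cbind(out_heads, z)
  }
  out_heads %*% wo
}

# exhaustive pair-counting AUC (concordant + half ties)
auc_pairs <- function(scores, pos) {
  ip <- which(pos); im <- which(!pos)
  s <- 0
  for (i in ip) for (j in im)
    s <- s + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  s / (length(ip) * length(im))
}

# small deterministic phantom cohort shared across trainer tests
tiny_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_cohort(phantom_config(), n = 24, seed = 417)
    cache
  }
})
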