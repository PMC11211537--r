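# Segmentation metrics: Dice similarity coefficient and average symmetric
# surface distance in millimetres under anisotropic voxel spacing.

#' Dice similarity coefficient
#'
#' `DSC(A, G) = 2|A n G| / (|A| + |G|)`.  Defined as 1 when both masks are
#' empty (perfect agreement on absence) and 0 when exactly one is empty.
#'
#' @param pred_mask,truth_mask binary arrays of identical shape.
#' @return DSC in `[0, 1]`, with voxel counts attached as attributes
#'   (`n_pred`, `n_truth`, `n_intersect`).
#' @export
dsc <- function(pred_mask, truth_mask) {
  if (!identical(dim(pred_mask), dim(truth_mask))) stop("shape mismatch")
  a <- sum(pred_mask != 0)
  g <- sum(truth_mask != 0)
  i <- sum(pred_mask != 0 & truth_mask != 0)
  val <- if (a + g == 0) 1 else 2 * i / (a + g)
  structure(val, n_pred = a, n_truth = g, n_intersect = i)
}

# surface voxels: mask voxels with at least one face-adjacent background
# voxel; voxels on the array border count as surface.
.surface <- function(mask) {
  m <- mask != 0
  dims <- dim(m)
  interior <- array(TRUE, dims)
  for (a in 1:3) {
    shift_up <- function(x, axis) {
      # neighbour at +1 along `axis`; FALSE beyond the border
      out <- array(FALSE, dims)
      n <- dims[axis]
      src <- lapply(dims, seq_len); dst <- lapply(dims, seq_len)
      src[[axis]] <- 2:n; dst[[axis]] <- 1:(n - 1)
      out[dst[[1]], dst[[2]], dst[[3]]] <- x[src[[1]], src[[2]], src[[3]]]
      out
    }
    shift_dn <- function(x, axis) {
      out <- array(FALSE, dims)
      n <- dims[axis]
      src <- lapply(dims, seq_len); dst <- lapply(dims, seq_len)
      src[[axis]] <- 1:(n - 1); dst[[axis]] <- 2:n
      out[dst[[1]], dst[[2]], dst[[3]]] <- x[src[[1]], src[[2]], src[[3]]]
      out
    }
    interior <- interior & shift_up(m, a) & shift_dn(m, a)
  }
  m & !interior
}

#' Average symmetric surface distance
#'
#' Mean Euclidean mm distance from each surface voxel of the predicted mask
#' to the nearest surface voxel of the reference mask, averaged with the
#' reverse direction.  Surface voxels are mask voxels with a face-adjacent
#' background voxel (6-neighbourhood); distances use the physical spacing
#' via an exact anisotropic Euclidean distance transform.
#'
#' @param pred_mask,truth_mask binary arrays of identical shape.
#' @param spacing mm triple (slice, row, column).
#' @return mean surface distance in mm, or `NA` (with a warning) when
#'   either mask is empty.
#' @export
asd <- function(pred_mask, truth_mask, spacing = c(1, 1, 1)) {
  if (!identical(dim(pred_mask), dim(truth_mask))) stop("shape mismatch")
  if (sum(pred_mask != 0) == 0 || sum(truth_mask != 0) == 0) {
    warning("ASD undefined for an empty mask")
    return(NA_real_)
  }
  sa <- .surface(pred_mask)
  sg <- .surface(truth_mask)
  dg <- sqrt(cpp_edt_sq(array(as.integer(sg), dim(sg)), dim(sg),
                        as.numeric(spacing)))
  da <- sqrt(cpp_edt_sq(array(as.integer(sa), dim(sa)), dim(sa),
                        as.numeric(spacing)))
  (mean(dg[sa]) + mean(da[sg])) / 2
}

#' Cohort-level segmentation score summary
#'
#' Scores every (prediction, reference) pair and summarises each metric by
#' its median, interquartile range (interpolated quartiles) and a seeded
#' bootstrap confidence interval of the median.
#'
#' @param cases list of lists with elements `pred`, `truth`, `spacing`
#'   (and optionally `case_id`).
#' @param level confidence level of the bootstrap CI.
#' @param boot number of bootstrap resamples.
#' @param seed integer seed for the bootstrap.
#' @return object of class `seg_scores`: `per_case` data frame
#'   (`case_id,dsc,asd_mm,vol_pred,vol_truth`) and `summary` data frame.
#' @export
score_cohort <- function(cases, level = 0.95, boot = 10000L, seed = 1L) {
  stopifnot(length(cases) >= 1L)
  per <- lapply(seq_along(cases), function(i) {
    cs <- cases[[i]]
    d <- dsc(cs$pred, cs$truth)
    a <- suppressWarnings(asd(cs$pred, cs$truth,
                              if (is.null(cs$spacing)) c(1, 1, 1)
                              else cs$spacing))
    data.frame(case_id = if (is.null(cs$case_id))
                 sprintf("case_%04d", i) else cs$case_id,
               dsc = as.numeric(d), asd_mm = a,
               vol_pred = attr(d, "n_pred"), vol_truth = attr(d, "n_truth"),
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  seed <- as.integer(seed)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  summ <- do.call(rbind, lapply(c("dsc", "asd_mm"), function(mname) {
    x <- per[[mname]]
    x <- x[!is.na(x)]
    if (length(x) == 0L)
      return(data.frame(metric = mname, n = 0L, median = NA_real_,
                        iqr = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_))
    med <- stats::median(x)
    iqr <- diff(stats::quantile(x, c(0.25, 0.75), names = FALSE))
    bm <- matrix(sample(x, boot * length(x), replace = TRUE), nrow = boot)
    meds <- apply(bm, 1L, stats::median)
    ci <- stats::quantile(meds, c((1 - level) / 2, 1 - (1 - level) / 2),
                          names = FALSE)
    data.frame(metric = mname, n = length(x), median = med, iqr = iqr,
               ci_lo = ci[1], ci_hi = ci[2])
  }))
  structure(list(per_case = per, summary = summ, level = level),
            class = "seg_scores")
}

#' @export
print.seg_scores <- function(x, ...) {
  cat(sprintf("Segmentation scores over %d cases\n", nrow(x$per_case)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
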