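# Preprocessing chain: resample -> z-score normalise -> crop/pad, plus the
# stratified k-fold split and NIfTI I/O.
#
# Axis convention, used everywhere in this package: internal 3D arrays are
# (slice, row, column) with 0-based half-open voxel indexing in the
# compiled kernels; spacing triples are mm per voxel in the same order.
# The clinical target resolution (rows/columns 0.4688 mm, slices 6 mm) is
# therefore written (6, 0.4688, 0.4688) internally.

#' Volume with spacing metadata
#'
#' @param data 3D numeric array (slice, row, column).
#' @param spacing numeric(3) mm per voxel, strictly positive.
#' @return object of class `volume_record`.
#' @export
volume_record <- function(data, spacing) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be 3 positive values")
  if (!all(is.finite(data))) stop("volume data must be finite")
  structure(list(data = data, spacing = as.numeric(spacing)),
            class = "volume_record")
}

.as_volume <- function(vol, spacing = NULL) {
  if (inherits(vol, "volume_record")) return(vol)
  volume_record(vol, spacing)
}

#' Read a NIfTI volume
#'
#' @param path path to a .nii or .nii.gz file.
#' @return a [volume_record()] with spacing taken from the NIfTI header
#'   (reordered to the internal slice, row, column convention).
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)
  arr <- aperm(unclass(as.array(img)), c(3, 1, 2))
  volume_record(arr, c(sp[3], sp[1], sp[2]))
}

#' Write a NIfTI volume
#'
#' @param data 3D array (slice, row, column) or [volume_record()].
#' @param spacing mm triple (ignored when `data` is a volume_record).
#' @param path output path (.nii or .nii.gz).
#' @export
write_volume <- function(data, spacing = NULL, path) {
  v <- .as_volume(data, spacing)
  arr <- aperm(v$data, c(2, 3, 1))       # row, column, slice on disk
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(v$spacing[2], v$spacing[3], v$spacing[1])
  RNifti::writeNifti(img, path)
  invisible(path)
}

# resample along one axis of a 3D array (axis 1 of the permuted view)
.resample_axis <- function(arr, axis, n_out, scale, method) {
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  inv <- order(perm)
  a <- if (axis == 1L) arr else aperm(arr, perm)
  a <- cpp_resample_axis1(a, dim(a), as.integer(n_out), scale,
                          as.integer(method))
  if (axis == 1L) a else aperm(a, inv)
}

#' Resample a volume to a target spacing
#'
#' Output grid size is `round(input_size * input_spacing / target_spacing)`
#' per axis.  In-plane axes use third-order (cubic) spline interpolation,
#' the slice axis uses nearest neighbour; masks are resampled nearest
#' neighbour on all axes so they stay strictly binary.
#'
#' @param vol a [volume_record()] (or array plus `spacing`).
#' @param target_spacing mm triple (slice, row, column), positive.
#' @param mask logical; `TRUE` forces nearest neighbour everywhere.
#' @param spacing input spacing when `vol` is a bare array.
#' @return a [volume_record()] at the target spacing.
#' @export
resample_volume <- function(vol, target_spacing, mask = FALSE,
                            spacing = NULL) {
  v <- .as_volume(vol, spacing)
  if (any(target_spacing <= 0)) stop("target spacing must be positive")
  in_sz <- dim(v$data)
  out_sz <- pmax(1L, as.integer(round(in_sz * v$spacing / target_spacing)))
  methods <- if (mask) c(0L, 0L, 0L) else c(0L, 1L, 1L)
  a <- v$data
  for (ax in 1:3) {
    if (out_sz[ax] == in_sz[ax] && target_spacing[ax] == v$spacing[ax])
      next
    a <- .resample_axis(a, ax, out_sz[ax],
                        scale = target_spacing[ax] / v$spacing[ax],
                        method = methods[ax])
  }
  if (mask) a <- array(as.integer(a != 0), dim(a))
  volume_record(a, as.numeric(target_spacing))
}

#' Z-score normalise a volume
#'
#' Subtracts the mean and divides by the population standard deviation, so
#' the output has mean 0 and SD 1.
#'
#' @param vol a [volume_record()] or 3D array.
#' @param spacing spacing when `vol` is a bare array.
#' @return normalised volume of the same class as the input.
#' @export
znormalize <- function(vol, spacing = c(1, 1, 1)) {
  v <- .as_volume(vol, spacing)
  x <- v$data
  mu <- mean(x)
  sdv <- sqrt(mean((x - mu)^2))
  if (sdv == 0) stop("degenerate input: constant volume")
  out <- (x - mu) / sdv
  if (inherits(vol, "volume_record")) volume_record(out, v$spacing)
  else out
}

#' Center crop or symmetric zero-pad to a target shape
#'
#' Crops centrally when an axis is larger than the target, zero-pads
#' symmetrically when smaller.  An optional `center` voxel (e.g. the mask
#' centroid at training time) shifts the crop window, clamped so the window
#' stays inside the volume.
#'
#' @param vol a [volume_record()] or 3D array.
#' @param target_shape integer(3).
#' @param center optional numeric(3) crop centre in voxel coordinates.
#' @param spacing spacing when `vol` is a bare array.
#' @return cropped/padded volume of the same class as the input.
#' @export
crop_or_pad <- function(vol, target_shape, center = NULL,
                        spacing = c(1, 1, 1)) {
  v <- .as_volume(vol, spacing)
  target_shape <- as.integer(target_shape)
  stopifnot(all(target_shape >= 1L))
  x <- v$data
  sz <- dim(x)
  if (is.null(center)) center <- (sz + 1) / 2
  out <- array(0, target_shape)
  src_start <- integer(3); src_end <- integer(3)
  dst_start <- integer(3); dst_end <- integer(3)
  for (a in 1:3) {
    if (sz[a] >= target_shape[a]) {
      s <- round(center[a] - target_shape[a] / 2)
      s <- min(max(1, s), sz[a] - target_shape[a] + 1)
      src_start[a] <- s; src_end[a] <- s + target_shape[a] - 1L
      dst_start[a] <- 1L; dst_end[a] <- target_shape[a]
    } else {
      p <- (target_shape[a] - sz[a]) %/% 2L
      src_start[a] <- 1L; src_end[a] <- sz[a]
      dst_start[a] <- p + 1L; dst_end[a] <- p + sz[a]
    }
  }
  out[dst_start[1]:dst_end[1], dst_start[2]:dst_end[2],
      dst_start[3]:dst_end[3]] <-
    x[src_start[1]:src_end[1], src_start[2]:src_end[2],
      src_start[3]:src_end[3]]
  if (inherits(vol, "volume_record")) volume_record(out, v$spacing)
  else out
}

#' Stratified k-fold assignment
#'
#' Partitions cases into `k` folds so that within every stage the fold
#' sizes differ by at most one case; deterministic for a fixed seed.
#'
#' @param labels integer stage per case (optionally named by case id).
#' @param k number of folds (>= 2, <= number of cases).
#' @param seed integer seed.
#' @return object of class `fold_assignment`: `fold` (integer vector in
#'   `0..k-1`, same order/names as `labels`) and `table` (per-fold
#'   per-stage counts).
#' @export
stratified_kfold <- function(labels, k = 3L, seed = 1L) {
  n <- length(labels)
  if (k < 2L) stop("k must be >= 2")
  if (k > n) stop("split error: k exceeds number of cases")
  seed <- as.integer(seed)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  fold <- integer(n)
  offset <- 0L
  for (s in sort(unique(labels))) {
    idx <- which(labels == s)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- (offset + seq_along(idx) - 1L) %% k
    offset <- (offset + length(idx)) %% k
  }
  names(fold) <- names(labels)
  structure(list(fold = fold, k = k,
                 table = table(stage = labels, fold = fold)),
            class = "fold_assignment")
}

#' @export
print.fold_assignment <- function(x, ...) {
  cat(sprintf("Stratified %d-fold assignment (%d cases)\n", x$k,
              length(x$fold)))
  print(x$table)
  invisible(x)
}

#' Preprocessing configuration
#'
#' The training-time image chain: resample to a common spacing (cubic
#' in-plane, nearest between slices; nearest everywhere for masks),
#' z-score normalise, then crop/pad to the network grid.  The crop is
#' centred on the mask centroid when a mask is available (training) and on
#' the volume centre otherwise.  `target_spacing = NULL` recomputes the
#' cohort median spacing at run time.
#'
#' @param target_spacing mm triple, or `NULL` for the cohort median.
#' @param crop_shape integer(3) network input grid.
#' @param normalize `"after_resample"` (default) or `"after_crop"`.
#' @return object of class `pre_config`.
#' @export
pre_config <- function(target_spacing = c(6, 1, 1),
                       crop_shape = c(10L, 24L, 24L),
                       normalize = c("after_resample", "after_crop")) {
  normalize <- match.arg(normalize)
  structure(list(target_spacing = target_spacing,
                 crop_shape = as.integer(crop_shape),
                 normalize = normalize),
            class = "pre_config")
}

.mask_centroid <- function(mask) {
  idx <- which(mask != 0, arr.ind = TRUE)
  colMeans(idx)
}

# Preprocess one phantom case (or image/mask pair) to the network grid.
# Returns list(image, mask, stage) on the crop grid, plus the grid spacing.
# Cases carrying a matching cached preparation (see prep_cohort) are
# returned directly.
.prep_case <- function(case, pre, use_centroid = TRUE) {
  key <- if (use_centroid) "prep_centroid" else "prep_center"
  if (!is.null(case[[key]]) && identical(case[[key]]$pre, pre))
    return(case[[key]]$prep)
  tsp <- pre$target_spacing
  img <- resample_volume(case$image, tsp, spacing = case$spacing)
  msk <- resample_volume(case$mask, tsp, mask = TRUE, spacing = case$spacing)
  if (pre$normalize == "after_resample") img <- znormalize(img)
  ctr <- if (use_centroid && sum(msk$data) > 0) .mask_centroid(msk$data)
         else NULL
  img <- crop_or_pad(img, pre$crop_shape, center = ctr)
  msk <- crop_or_pad(msk, pre$crop_shape, center = ctr)
  if (pre$normalize == "after_crop") img <- znormalize(img)
  list(image = img$data, mask = array(as.integer(msk$data != 0),
                                      dim(msk$data)),
       stage = case$stage, spacing = tsp, case_id = case$case_id)
}

#' Precompute the preprocessing chain for a cohort
#'
#' Attaches the preprocessed (resampled, normalised, cropped) image/mask to
#' every case, in both the training variant (crop centred on the mask
#' centroid) and the inference variant (volume-centre crop), so repeated
#' fits on the same cohort skip the chain.
#'
#' @param cases list of phantom cases.
#' @param pre a [pre_config()].
#' @return the case list with cached preparations attached.
#' @export
prep_cohort <- function(cases, pre = pre_config()) {
  lapply(cases, function(cc) {
    cc$prep_centroid <- list(pre = pre,
                             prep = .prep_case(cc, pre, use_centroid = TRUE))
    cc$prep_center <- list(pre = pre,
                           prep = .prep_case(cc, pre, use_centroid = FALSE))
    cc
  })
}
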