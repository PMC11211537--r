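# Synthetic 3D phantom cohort generator.
#
# Each phantom is a "head": nested ellipsoidal shells around a core cavity
# (the nasopharynx), with a connected tumor grown from the core by
# randomized 6-neighbourhood accretion.  The ground-truth T stage is a pure
# function of how deep the tumor invades the shells, so segmentation and
# staging are jointly learnable and every label is recomputable from the
# emitted mask.  Voxels are anisotropic: coarse between slices, fine
# in-plane, as in clinical head-and-neck MR.

#' Build a nested-shell anatomy atlas
#'
#' Creates an integer label volume with values 0 (outside the head),
#' 1 (core cavity), and 2-4 (progressively deeper shells around the core).
#' Shells are nested ellipsoids; the seed jitters their centre and radii
#' slightly so atlases differ across cohorts while remaining deterministic.
#'
#' @param shape integer(3) grid (slices, rows, columns); every dim >= 8.
#' @param spacing numeric(3) voxel size in mm (slice, row, column).
#' @param seed integer seed.
#' @return object of class `shell_atlas` with fields `shape`, `regions`,
#'   `spacing`, `seed`.
#' @export
build_atlas <- function(shape = c(16L, 64L, 64L),
                        spacing = c(6, 0.5, 0.5), seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 8L))
    stop("atlas shape must have all dims >= 8")
  stopifnot(length(spacing) == 3L, all(spacing > 0))
  seed <- as.integer(seed)          # force before saving the RNG state
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  ctr <- (shape + 1) / 2 + stats::runif(3, -0.02, 0.02) * shape
  rad <- 0.45 * shape * (1 + stats::runif(3, -0.05, 0.05))  # voxel units
  dz <- ((seq_len(shape[1]) - ctr[1]) / rad[1])^2
  dy <- ((seq_len(shape[2]) - ctr[2]) / rad[2])^2
  dx <- ((seq_len(shape[3]) - ctr[3]) / rad[3])^2
  rho2 <- outer(outer(dz, dy, `+`), dx, `+`)
  rho <- sqrt(rho2)
  cuts <- c(0.35, 0.55, 0.75)
  regions <- array(0L, shape)
  regions[rho <= 1] <- 4L
  regions[rho < cuts[3]] <- 3L
  regions[rho < cuts[2]] <- 2L
  regions[rho < cuts[1]] <- 1L
  structure(list(shape = shape, regions = regions, spacing = spacing,
                 seed = seed, rho = rho, cuts = cuts),
            class = "shell_atlas")
}

#' Grow a connected tumor inside an atlas
#'
#' Randomized region growing: a seed voxel is drawn inside the core cavity
#' and the region accretes one randomly drawn frontier voxel at a time
#' (6-neighbourhood, restricted to the head) until it reaches
#' `target_volume` voxels.  Frontier voxels are drawn with probability
#' proportional to the inverse voxel spacing of the face they were reached
#' through, so growth is approximately isotropic in millimetres despite the
#' anisotropic grid.  The seed voxel is drawn from the inner half of the
#' core cavity (the tumor's site of origin), which ties the final volume
#' tightly to the invasion depth.
#'
#' @param atlas a [build_atlas()] object.
#' @param target_volume integer number of tumor voxels (>= 1 and no more
#'   than the voxels reachable from the core).
#' @param seed integer seed.
#' @return binary integer array of the atlas shape.
#' @export
grow_tumor <- function(atlas, target_volume, seed = 1L) {
  stopifnot(inherits(atlas, "shell_atlas"))
  dims <- atlas$shape
  inside <- atlas$regions > 0L
  n_reach <- sum(inside)
  if (target_volume < 1 || target_volume > n_reach)
    stop(sprintf("growth failure: target volume %d outside [1, %d]",
                 target_volume, n_reach))
  seed <- as.integer(seed)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  D <- dims[1]; H <- dims[2]; W <- dims[3]
  tumor <- logical(length(inside))
  in_cand <- logical(length(inside))
  core <- which(atlas$regions == 1L & atlas$rho < 0.5 * atlas$cuts[1])
  if (length(core) == 0L) core <- which(atlas$regions == 1L)
  start <- core[sample.int(length(core), 1L)]
  axw <- (1 / atlas$spacing) / max(1 / atlas$spacing)
  cand <- integer(256L); cw <- numeric(256L); nc <- 0L
  push_nb <- function(li) {
    d <- ((li - 1L) %% D) + 1L
    h <- (((li - 1L) %/% D) %% H) + 1L
    w <- ((li - 1L) %/% (D * H)) + 1L
    nb <- integer(0); nw <- numeric(0)
    if (d > 1L) { nb <- c(nb, li - 1L); nw <- c(nw, axw[1]) }
    if (d < D) { nb <- c(nb, li + 1L); nw <- c(nw, axw[1]) }
    if (h > 1L) { nb <- c(nb, li - D); nw <- c(nw, axw[2]) }
    if (h < H) { nb <- c(nb, li + D); nw <- c(nw, axw[2]) }
    if (w > 1L) { nb <- c(nb, li - D * H); nw <- c(nw, axw[3]) }
    if (w < W) { nb <- c(nb, li + D * H); nw <- c(nw, axw[3]) }
    keep <- inside[nb] & !tumor[nb] & !in_cand[nb]
    nb <- nb[keep]; nw <- nw[keep]
    if (length(nb)) {
      if (nc + length(nb) > length(cand)) {
        length(cand) <<- 2L * (nc + length(nb))
        length(cw) <<- length(cand)
      }
      cand[(nc + 1L):(nc + length(nb))] <<- nb
      cw[(nc + 1L):(nc + length(nb))] <<- nw
      in_cand[nb] <<- TRUE
      nc <<- nc + length(nb)
    }
  }
  tumor[start] <- TRUE
  push_nb(start)
  grown <- 1L
  while (grown < target_volume) {
    if (nc == 0L)
      stop("growth failure: frontier exhausted before target volume")
    j <- sample.int(nc, 1L, prob = cw[seq_len(nc)])
    li <- cand[j]
    cand[j] <- cand[nc]; cw[j] <- cw[nc]; nc <- nc - 1L
    in_cand[li] <- FALSE
    tumor[li] <- TRUE
    grown <- grown + 1L
    push_nb(li)
  }
  array(as.integer(tumor), dims)
}

#' Derive the T stage from tumor/atlas overlap
#'
#' The stage is the deepest shell the tumor invades: the largest band label
#' `b` in 2..4 whose cumulative overlap fraction
#' `|mask intersect (bands >= b)| / |mask|` reaches `thresholds[b-1]`,
#' or 1 when no band is invaded.  Cumulative fractions make the rule
#' monotone: growing the tumor at or beyond its current invasion depth can
#' never lower the stage.
#'
#' @param mask binary array (nonempty), same shape as the atlas.
#' @param atlas a [build_atlas()] object.
#' @param thresholds numeric(3), invasion fraction required for bands
#'   2, 3, 4.
#' @return integer stage in 1..4.
#' @export
stage_from_overlap <- function(mask, atlas, thresholds = c(0.05, 0.05, 0.05)) {
  stopifnot(inherits(atlas, "shell_atlas"))
  if (!identical(dim(mask), dim(atlas$regions))) stop("shape mismatch")
  n <- sum(mask != 0)
  if (n == 0) stop("invalid case: empty mask")
  stage <- 1L
  for (b in 2:4) {
    frac <- sum(mask != 0 & atlas$regions >= b) / n
    if (frac >= thresholds[b - 1L]) stage <- b
  }
  stage
}

#' Phantom cohort configuration
#'
#' Defaults encode the study conditions the generator emulates: the
#' four-stage class imbalance (8/44/27/21%), stage-monotone tumor volume
#' ranges, anisotropic voxels, a low-frequency background texture below the
#' tumor contrast, a smooth bias field and additive Gaussian noise.
#'
#' @param shape,spacing grid and voxel size handed to [build_atlas()].
#' @param mixture stage mixture proportions (4 values summing to 1).
#' @param volume_ranges 4x2 matrix of tumor voxel-count ranges per stage;
#'   rows must be nondecreasing with stage.
#' @param thresholds invasion fractions for [stage_from_overlap()].
#' @param noise_sd Gaussian noise standard deviation.
#' @param contrast additive tumor intensity offset.
#' @param texture_amp background texture amplitude (SD of the random field).
#' @param bias_amp bias-field amplitude.
#' @param base_level,outside_level head / air base intensities.
#' @return object of class `phantom_config`.
#' @export
phantom_config <- function(shape = c(16L, 64L, 64L),
                           spacing = c(6, 0.5, 0.5),
                           mixture = c(0.08, 0.44, 0.27, 0.21),
                           volume_ranges = rbind(c(60, 140),
                                                 c(250, 700),
                                                 c(1300, 2600),
                                                 c(4200, 6500)),
                           thresholds = c(0.05, 0.05, 0.05),
                           noise_sd = 0.2, contrast = 1,
                           texture_amp = 0.3, bias_amp = 0.2,
                           base_level = 1, outside_level = 0) {
  stopifnot(length(mixture) == 4L, all(mixture >= 0))
  if (abs(sum(mixture) - 1) > 1e-9)
    stop("mixture proportions must sum to 1")
  volume_ranges <- matrix(as.numeric(volume_ranges), 4L, 2L)
  if (any(diff(volume_ranges[, 1]) < 0) || any(diff(volume_ranges[, 2]) < 0))
    stop("volume ranges must be nondecreasing with stage")
  structure(list(shape = as.integer(shape), spacing = spacing,
                 mixture = mixture, volume_ranges = volume_ranges,
                 thresholds = thresholds, noise_sd = noise_sd,
                 contrast = contrast, texture_amp = texture_amp,
                 bias_amp = bias_amp, base_level = base_level,
                 outside_level = outside_level),
            class = "phantom_config")
}

# smooth zero-mean random field: coarse white noise trilinearly upsampled,
# rescaled to unit SD then to the requested amplitude
.random_field <- function(dims, coarse, amp) {
  cg <- pmax(2L, as.integer(ceiling(dims / coarse)))
  f <- array(stats::rnorm(prod(cg)), c(1L, cg))
  f <- cpp_resize3_fwd(f, dim(f), as.integer(dims))
  f <- array(f, dims)
  f <- f - mean(f)
  s <- stats::sd(f)
  if (s == 0) return(array(0, dims))
  f / s * amp
}

# Synthesize one phantom case on a fixed atlas.  Rejection-samples the
# tumor volume within the desired stage's range until the derived stage
# matches (the stored stage is ALWAYS re-derived from the mask).
.make_case <- function(atlas, config, want_stage, case_id, case_seed,
                       keep_components = FALSE, max_tries = 40L) {
  case_seed <- as.integer(case_seed)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(case_seed)
  rng <- config$volume_ranges[want_stage, ]
  mask <- NULL
  for (try in seq_len(max_tries)) {
    tv <- as.integer(round(stats::runif(1, rng[1], rng[2])))
    gseed <- sample.int(.Machine$integer.max - 1L, 1L)
    m <- grow_tumor(atlas, tv, seed = gseed)
    st <- stage_from_overlap(m, atlas, config$thresholds)
    mask <- m
    if (st == want_stage) break
  }
  stage <- stage_from_overlap(mask, atlas, config$thresholds)
  dims <- atlas$shape
  head <- atlas$regions > 0L
  base <- ifelse(head, config$base_level, config$outside_level)
  texture <- .random_field(dims, c(4, 8, 8), config$texture_amp) *
    head * (1 - mask)
  bias <- .random_field(dims, c(8, 24, 24), config$bias_amp)
  noise <- array(stats::rnorm(prod(dims), 0, config$noise_sd), dims)
  image <- base + texture + bias + config$contrast * mask + noise
  case <- structure(list(image = image, mask = mask, stage = stage,
                         spacing = config$spacing, case_id = case_id,
                         seed = case_seed),
                    class = "phantom_case")
  if (keep_components)
    case$components <- list(base = base, texture = texture, bias = bias,
                            noise = noise)
  case
}

#' Generate a phantom cohort
#'
#' Draws `n` cases with stages sampled from the configured mixture, grows a
#' matching tumor for each, and synthesizes the image as background texture
#' + tumor contrast + smooth bias field + Gaussian noise.  Every stored
#' stage equals `stage_from_overlap(mask, atlas)` by construction.
#'
#' @param config a [phantom_config()].
#' @param n number of cases (>= 4).
#' @param seed integer seed; the full cohort (atlas, stages, tumors,
#'   intensities, manifest) is deterministic in it.
#' @param out_dir optional directory: cases are written as NIfTI image/mask
#'   pairs plus a `manifest.csv` (`case_id,stage,seed,volume_voxels`).
#' @param keep_components if `TRUE` each case retains its additive image
#'   components (base, texture, bias, noise) for diagnostics.
#' @return object of class `phantom_cohort`: list with `cases`, `atlas`,
#'   `manifest`, `config`.
#' @export
generate_cohort <- function(config = phantom_config(), n, seed = 1L,
                            out_dir = NULL, keep_components = FALSE) {
  stopifnot(inherits(config, "phantom_config"))
  if (n < 4) stop("n must be >= 4")
  seed <- as.integer(seed)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  atlas <- build_atlas(config$shape, config$spacing,
                       seed = sample.int(.Machine$integer.max - 1L, 1L))
  stages <- sample.int(4L, n, replace = TRUE, prob = config$mixture)
  case_seeds <- sample.int(.Machine$integer.max - 1L, n)
  cases <- vector("list", n)
  for (i in seq_len(n)) {
    cases[[i]] <- .make_case(atlas, config, stages[i],
                             sprintf("case_%04d", i), case_seeds[i],
                             keep_components = keep_components)
  }
  manifest <- data.frame(
    case_id = vapply(cases, `[[`, character(1), "case_id"),
    stage = vapply(cases, `[[`, integer(1), "stage"),
    seed = vapply(cases, `[[`, integer(1), "seed"),
    volume_voxels = vapply(cases, function(cc) sum(cc$mask), integer(1)),
    stringsAsFactors = FALSE)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir) &&
        !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
      stop("cannot create output directory: ", out_dir)
    for (cc in cases) {
      write_volume(cc$image, config$spacing,
                   file.path(out_dir, paste0(cc$case_id, "_img.nii.gz")))
      write_volume(cc$mask, config$spacing,
                   file.path(out_dir, paste0(cc$case_id, "_msk.nii.gz")))
    }
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  structure(list(cases = cases, atlas = atlas, manifest = manifest,
                 config = config, seed = seed),
            class = "phantom_cohort")
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat(sprintf("Phantom cohort: %d cases on a %s grid @ (%s) mm\n",
              nrow(x$manifest), paste(x$config$shape, collapse = "x"),
              paste(x$config$spacing, collapse = ", ")))
  print(table(stage = x$manifest$stage))
  invisible(x)
}
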