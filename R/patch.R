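#' Sampler configuration for patch-based training
#'
#' Holds the patch geometry and the parameters of the two training-time
#' samplers: the mining-batch composer (a batch of `mining_batch_size`
#' patches of which `positive_fraction` are forced to contain a new-lesion
#' voxel) and the fixed oversampler (each patch is forced-positive
#' independently with probability `oversample_p`).
#'
#' @param patch_size cubic patch edge in voxels (default 32).
#' @param oversample_p probability `p` in `[0, 1]` of drawing a
#'   forced-positive patch in the oversampling strategy.
#' @param mining_batch_size the mining batch size (default 128).
#' @param train_batch_size the training batch size (default 32); must not
#'   exceed `mining_batch_size`.
#' @param positive_fraction fraction of forced-positive patches in the
#'   mining batch (default 0.3); the count is
#'   `floor(positive_fraction * mining_batch_size)`.
#' @param seed integer seed recorded for reproducibility logs.
#' @return an object of class `sampler_config`.
#' @export
sampler_config <- function(patch_size = 32L, oversample_p = 0.5,
                           mining_batch_size = 128L, train_batch_size = 32L,
                           positive_fraction = 0.3, seed = 0L) {
  if (train_batch_size > mining_batch_size)
    stopf("sampler_config: train_batch_size must be <= mining_batch_size")
  if (positive_fraction < 0 || positive_fraction > 1)
    stopf("sampler_config: positive_fraction must be in [0, 1]")
  if (oversample_p < 0 || oversample_p > 1)
    stopf("sampler_config: oversample_p must be in [0, 1]")
  structure(list(patch_size = as.integer(patch_size),
                 oversample_p = as.double(oversample_p),
                 mining_batch_size = as.integer(mining_batch_size),
                 train_batch_size = as.integer(train_batch_size),
                 positive_fraction = as.double(positive_fraction),
                 seed = as.integer(seed)),
            class = "sampler_config")
}

#' Build the sliding-window inference grid
#'
#' Per axis the starts are `1, 1 + stride, 1 + 2 stride, ...`; any start
#' whose patch would overrun the axis is replaced by `len - patch + 1`
#' (edge clamping), duplicates removed. The 3D grid is the Cartesian
#' product, so every voxel is covered by at least one patch. With patch 32
#' and stride 24 consecutive stride-spaced patches overlap by 8 voxels.
#'
#' @param shape integer triple of volume dimensions.
#' @param patch patch edge (default 32).
#' @param stride grid stride (default 24).
#' @return integer matrix with one row per patch and columns `d, h, w`
#'   (1-based start indices).
#' @export
build_patch_grid <- function(shape, patch = 32L, stride = 24L) {
  shape <- as.integer(shape)
  if (any(shape < patch))
    stopf("build_patch_grid: axis length %d < patch %d; pad the volume first",
          min(shape), patch)
  axis_starts <- function(len) {
    s <- seq.int(1L, len, by = stride)
    s[s + patch - 1L > len] <- len - patch + 1L
    sort(unique(as.integer(s)))
  }
  g <- expand.grid(d = axis_starts(shape[1]), h = axis_starts(shape[2]),
                   w = axis_starts(shape[3]), KEEP.OUT.ATTRS = FALSE)
  as.matrix(g)
}

#' Index the positive voxels of a ground-truth mask
#'
#' @param gt_mask binary 3D array or [volume3d()].
#' @param patch unused placeholder kept for interface symmetry.
#' @return integer matrix of positive voxel coordinates (one row per voxel);
#'   zero rows when the mask is empty.
#' @export
index_positive_patches <- function(gt_mask, patch = 32L) {
  m <- if (inherits(gt_mask, "volume3d")) gt_mask$data else gt_mask
  vals <- unique(as.vector(m))
  if (!all(vals %in% c(0, 1)))
    stopf("index_positive_patches: mask is not binary (values %s)",
          paste(utils::head(sort(vals), 5), collapse = ", "))
  which(m == 1, arr.ind = TRUE)
}

# Internal: turn a longitudinal_case into the in-memory training
# representation (z-scored stacked intensities + positive-voxel index).
prepare_case <- function(case, normalize = TRUE) {
  stopifnot(inherits(case, "longitudinal_case"))
  b <- case$baseline; f <- case$followup
  if (normalize) { b <- zscore_normalize(b); f <- zscore_normalize(f) }
  st <- stack_timepoints(b, f)
  gt <- case$gt_mask$data
  list(patient_id = case$patient_id, x = st$data, gt = gt,
       pos = index_positive_patches(gt), shape = dim(gt),
       voxel_size_mm = case$gt_mask$voxel_size_mm)
}

new_patch_ref <- function(case_idx, case_id, start, size, is_positive) {
  list(case = case_idx, case_id = case_id, start = as.integer(start),
       size = as.integer(size), is_positive = isTRUE(is_positive))
}

patch_contains_positive <- function(pc, start, patch) {
  if (nrow(pc$pos) == 0L) return(FALSE)
  e <- start + patch - 1L
  any(pc$pos[, 1] >= start[1] & pc$pos[, 1] <= e[1] &
      pc$pos[, 2] >= start[2] & pc$pos[, 2] <= e[2] &
      pc$pos[, 3] >= start[3] & pc$pos[, 3] <= e[3])
}

#' Sample a forced-positive patch from a case
#'
#' Picks a uniformly random ground-truth-positive voxel, then a uniformly
#' random valid patch start such that the voxel lies inside the patch and
#' the patch inside the volume. Uniform placement over all containing
#' starts avoids biasing lesions toward patch centers.
#'
#' @param pc a prepared case (internal representation from the training
#'   pipeline) or a `longitudinal_case`.
#' @param patch patch edge.
#' @return a patch reference (list with `case_id`, `start`, `size`,
#'   `is_positive = TRUE`).
#' @export
sample_positive_patch <- function(pc, patch = 32L) {
  if (inherits(pc, "longitudinal_case")) pc <- prepare_case(pc)
  if (nrow(pc$pos) == 0L)
    stopf("sample_positive_patch: case %s has no positive voxels", pc$patient_id)
  v <- pc$pos[sample.int(nrow(pc$pos), 1L), ]
  lo <- pmax(1L, v - patch + 1L)
  hi <- pmin(v, pc$shape - patch + 1L)
  start <- lo + vapply(hi - lo, function(k) sample.int(k + 1L, 1L) - 1L,
                       integer(1))
  new_patch_ref(NA_integer_, pc$patient_id, start, patch, TRUE)
}

sample_uniform_patch <- function(pc, patch) {
  hi <- pc$shape - patch + 1L
  start <- vapply(hi, function(k) sample.int(k, 1L), integer(1))
  new_patch_ref(NA_integer_, pc$patient_id, start, patch,
                patch_contains_positive(pc, start, patch))
}

#' Compose a mining batch (30/70 forced-positive/uniform)
#'
#' Draws exactly `floor(positive_fraction * mining_batch_size)`
#' forced-positive patches and fills the rest with patches whose starts are
#' uniform over all valid positions of a uniformly chosen case (these may
#' still be positive by chance). Cases without positive voxels are skipped
#' for the forced-positive draws; if no case has positives the whole batch
#' is uniform and a warning is raised.
#'
#' @param cfg a [sampler_config()].
#' @param cases list of prepared cases or `longitudinal_case`s.
#' @return list of `mining_batch_size` patch references.
#' @export
compose_mining_batch <- function(cfg, cases) {
  stopifnot(inherits(cfg, "sampler_config"))
  cases <- lapply(cases, function(cs)
    if (inherits(cs, "longitudinal_case")) prepare_case(cs) else cs)
  n_pos <- floor(cfg$positive_fraction * cfg$mining_batch_size)
  has_pos <- which(vapply(cases, function(cs) nrow(cs$pos) > 0L, logical(1)))
  if (length(has_pos) == 0L && n_pos > 0L) {
    warning("compose_mining_batch: no case has positive voxels; sampling all-uniform")
    n_pos <- 0L
  }
  refs <- vector("list", cfg$mining_batch_size)
  for (i in seq_len(n_pos)) {
    ci <- has_pos[sample.int(length(has_pos), 1L)]
    r <- sample_positive_patch(cases[[ci]], cfg$patch_size)
    r$case <- ci
    refs[[i]] <- r
  }
  for (i in seq.int(n_pos + 1L, length.out = cfg$mining_batch_size - n_pos)) {
    ci <- sample.int(length(cases), 1L)
    r <- sample_uniform_patch(cases[[ci]], cfg$patch_size)
    r$case <- ci
    refs[[i]] <- r
  }
  refs
}

#' Sample a training batch with fixed positive oversampling
#'
#' Each of the `train_batch_size` patches is, independently, a
#' forced-positive patch with probability `oversample_p` and a uniform
#' patch otherwise (which may still be positive by chance). `p = 0` is the
#' pure uniform arm.
#'
#' @inheritParams compose_mining_batch
#' @return list of `train_batch_size` patch references.
#' @export
sample_oversampled_batch <- function(cfg, cases) {
  stopifnot(inherits(cfg, "sampler_config"))
  cases <- lapply(cases, function(cs)
    if (inherits(cs, "longitudinal_case")) prepare_case(cs) else cs)
  has_pos <- which(vapply(cases, function(cs) nrow(cs$pos) > 0L, logical(1)))
  warn_once <- length(has_pos) == 0L && cfg$oversample_p > 0
  if (warn_once)
    warning("sample_oversampled_batch: no case has positive voxels; sampling all-uniform")
  lapply(seq_len(cfg$train_batch_size), function(i) {
    forced <- length(has_pos) > 0L && runif(1) < cfg$oversample_p
    if (forced) {
      ci <- has_pos[sample.int(length(has_pos), 1L)]
      r <- sample_positive_patch(cases[[ci]], cfg$patch_size)
    } else {
      ci <- sample.int(length(cases), 1L)
      r <- sample_uniform_patch(cases[[ci]], cfg$patch_size)
    }
    r$case <- ci
    r
  })
}

# Internal: materialize patch references into network tensors.
# Returns x (p, p, p, 2, B) and y (p, p, p, 1, B).
extract_batch <- function(cases, refs, patch) {
  B <- length(refs)
  x <- array(0, dim = c(patch, patch, patch, 2L, B))
  y <- array(0, dim = c(patch, patch, patch, 1L, B))
  for (i in seq_len(B)) {
    r <- refs[[i]]
    pc <- cases[[r$case]]
    s <- r$start; e <- s + patch - 1L
    x[, , , , i] <- pc$x[s[1]:e[1], s[2]:e[2], s[3]:e[3], ]
    y[, , , 1L, i] <- pc$gt[s[1]:e[1], s[2]:e[2], s[3]:e[3]]
  }
  list(x = x, y = y)
}
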