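#' A 3D volume with voxel spacing and world affine
#'
#' Lightweight container used throughout the pipeline: a numeric 3D array
#' (D x H x W), the voxel spacing in millimetres per axis, and a 4x4 world
#' affine whose first three column norms agree with the spacing.
#'
#' @param data numeric 3D array.
#' @param voxel_size_mm positive numeric of length 1 or 3 (mm per voxel).
#' @param affine optional 4x4 affine; defaults to `diag(voxel)` with zero
#'   origin.
#' @return an object of class `volume3d`.
#' @export
volume3d <- function(data, voxel_size_mm = 1, affine = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stopf("volume3d: `data` must be a 3D array, got %s dims",
          length(dim(data)) %||% 0L)
  if (!all(is.finite(data))) stopf("volume3d: data contains non-finite values")
  vs <- as.double(voxel_size_mm)
  if (length(vs) == 1L) vs <- rep(vs, 3L)
  if (length(vs) != 3L || any(vs <= 0))
    stopf("volume3d: voxel_size_mm must be 1 or 3 positive values")
  if (is.null(affine)) {
    affine <- diag(c(vs, 1))
  } else {
    affine <- as.matrix(affine)
    if (!all(dim(affine) == c(4L, 4L))) stopf("volume3d: affine must be 4x4")
    cn <- sqrt(colSums(affine[1:3, 1:3]^2))
    if (any(abs(cn - vs) > 1e-3))
      stopf("volume3d: affine column norms (%.4f, %.4f, %.4f) disagree with voxel_size_mm",
            cn[1], cn[2], cn[3])
  }
  structure(list(data = data, voxel_size_mm = vs, affine = affine),
            class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume3d> %d x %d x %d voxels @ (%.3g, %.3g, %.3g) mm\n",
              d[1], d[2], d[3],
              x$voxel_size_mm[1], x$voxel_size_mm[2], x$voxel_size_mm[3]))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.volume3d <- function(x) dim(x$data)

as_volume3d <- function(x, like = NULL) {
  if (inherits(x, "volume3d")) return(x)
  volume3d(x,
           voxel_size_mm = if (is.null(like)) 1 else like$voxel_size_mm,
           affine = if (is.null(like)) NULL else like$affine)
}

#' Read a 3D NIfTI volume
#'
#' Reads a NIfTI-1/2 file, reorients it to the canonical RAS axis order so
#' that co-registered baseline/follow-up grids align, and returns a
#' [volume3d()] carrying the header's voxel spacing and affine.
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @return a [volume3d()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stopf("read_volume: file not found: %s", path)
  img <- RNifti::readNifti(path)
  orient <- try(RNifti::orientation(img), silent = TRUE)
  if (!inherits(orient, "try-error") && !identical(orient, "RAS")) {
    RNifti::orientation(img) <- "RAS"
  }
  dm <- dim(img)
  if (length(dm) != 3L)
    stopf("read_volume: expected 3D volume, got %dD image at %s",
          length(dm), path)
  pd <- RNifti::pixdim(img)
  if (length(pd) < 3L || any(!is.finite(pd[1:3])) || any(pd[1:3] <= 0))
    stopf("read_volume: header pixdim of %s has no valid 3D spacing", path)
  aff <- try(structure(RNifti::xform(img), class = NULL), silent = TRUE)
  arr <- array(as.double(img), dim = dm)
  if (inherits(aff, "try-error")) {
    volume3d(arr, voxel_size_mm = pd[1:3])
  } else {
    # qform sign conventions can flip column signs; norms still match spacing
    volume3d(arr, voxel_size_mm = pd[1:3], affine = aff)
  }
}

#' Write a volume to NIfTI-1
#'
#' @param v a [volume3d()].
#' @param path output path (`.nii.gz` recommended).
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  stopifnot(inherits(v, "volume3d"))
  img <- RNifti::asNifti(v$data)
  RNifti::pixdim(img) <- v$voxel_size_mm
  ok <- try(RNifti::writeNifti(img, path), silent = TRUE)
  if (inherits(ok, "try-error"))
    stopf("write_volume: failed to write %s", path)
  invisible(path)
}

#' Resample a volume to isotropic voxels
#'
#' Resamples onto an isotropic grid of `target_mm` voxels covering the same
#' field of view. The output shape per axis is
#' `round(shape * spacing / target_mm)` (round-half-to-even, so shapes are
#' reproducible across platforms). Images use trilinear interpolation; binary
#' masks should use `method = "nearest"` to stay binary.
#'
#' @param v a [volume3d()].
#' @param target_mm positive scalar, default 0.5 mm.
#' @param method `"trilinear"` (default) or `"nearest"`.
#' @return a [volume3d()] with spacing `c(target_mm, target_mm, target_mm)`.
#' @export
resample_isotropic <- function(v, target_mm = 0.5,
                               method = c("trilinear", "nearest")) {
  stopifnot(inherits(v, "volume3d"))
  method <- match.arg(method)
  if (!is.numeric(target_mm) || length(target_mm) != 1L || target_mm <= 0)
    stopf("resample_isotropic: target_mm must be a positive scalar")
  in_dim <- dim(v$data)
  in_sp <- v$voxel_size_mm
  out_dim <- pmax(1L, as.integer(round(in_dim * in_sp / target_mm)))
  out <- resample3d_cpp(as.double(v$data), as.integer(in_dim),
                        as.double(in_sp), as.integer(out_dim),
                        rep(as.double(target_mm), 3L),
                        nearest = identical(method, "nearest"))
  volume3d(out, voxel_size_mm = rep(target_mm, 3L))
}

#' Z-score normalize a volume
#'
#' Centers and scales intensities to mean 0, SD 1 over all voxels of the
#' image (no brain mask is used). A volume with SD below `1e-8` is returned
#' as all zeros with a warning rather than an error.
#'
#' @param v a [volume3d()] (or plain 3D array).
#' @return a [volume3d()] with the same spacing.
#' @export
zscore_normalize <- function(v) {
  v <- as_volume3d(v)
  mu <- mean(v$data)
  sg <- sd(as.vector(v$data))
  if (!is.finite(sg) || sg < 1e-8) {
    warning("zscore_normalize: near-constant volume, returning all zeros")
    out <- array(0, dim = dim(v$data))
  } else {
    out <- (v$data - mu) / sg
  }
  volume3d(out, voxel_size_mm = v$voxel_size_mm, affine = v$affine)
}

#' Stack baseline and follow-up into a two-channel input
#'
#' Concatenates the two timepoints along a leading channel axis, producing
#' the 2 x D x H x W tensor the network consumes. Channel 1 is the baseline,
#' channel 2 the follow-up (fixed order).
#'
#' @param baseline,followup [volume3d()] objects on the same grid (shape
#'   equal, spacing within 1e-3 mm).
#' @return an object of class `stacked_input` with fields `data`
#'   (D x H x W x 2 array, channel-last storage; see Details) and
#'   `voxel_size_mm`.
#' @details Storage is channel-last (`dim = c(D, H, W, 2)`) because R arrays
#'   are column-major; the logical channel-first contract (channel 0 =
#'   baseline) is preserved by indexing `x$data[, , , k]`.
#' @export
stack_timepoints <- function(baseline, followup) {
  baseline <- as_volume3d(baseline)
  followup <- as_volume3d(followup)
  db <- dim(baseline$data); df <- dim(followup$data)
  if (!all(db == df))
    stopf("stack_timepoints: shape mismatch %s vs %s",
          paste(db, collapse = "x"), paste(df, collapse = "x"))
  if (any(abs(baseline$voxel_size_mm - followup$voxel_size_mm) > 1e-3))
    stopf("stack_timepoints: voxel spacing mismatch (%s vs %s mm)",
          paste(signif(baseline$voxel_size_mm, 4), collapse = ","),
          paste(signif(followup$voxel_size_mm, 4), collapse = ","))
  x <- array(0, dim = c(db, 2L))
  x[, , , 1L] <- baseline$data
  x[, , , 2L] <- followup$data
  structure(list(data = x, voxel_size_mm = baseline$voxel_size_mm),
            class = "stacked_input")
}

#' Full two-timepoint preprocessing
#'
#' Resample both timepoints to an isotropic grid, z-score normalize each
#' individually, and stack them channel-wise. With `target_mm = NULL` the
#' volumes are kept on their native grid (useful when data are already
#' isotropic).
#'
#' @inheritParams stack_timepoints
#' @param target_mm isotropic target spacing in mm, or `NULL` to skip
#'   resampling.
#' @return a `stacked_input`.
#' @export
preprocess_case <- function(baseline, followup, target_mm = 0.5) {
  if (!is.null(target_mm)) {
    baseline <- resample_isotropic(baseline, target_mm)
    followup <- resample_isotropic(followup, target_mm)
  }
  stack_timepoints(zscore_normalize(baseline), zscore_normalize(followup))
}
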