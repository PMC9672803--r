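#' Parameters for the synthetic longitudinal volume generator
#'
#' The generator emulates the statistical structure a two-timepoint
#' new-lesion segmenter is trained on: a shared brain-like background with
#' smooth random texture, stable hyperintense lesions present at both
#' timepoints, new hyperintense lesions present only at follow-up, and an
#' extreme voxel class imbalance (of the order of 0.005\% positive voxels
#' with the defaults).
#'
#' When `target_positive_fraction` is supplied (or neither it nor
#' `n_new_lesions` is, in which case it defaults to `5e-5`), the number of
#' new lesions is solved from the target at the fixed mean radius of
#' `new_lesion_radius_range_mm`, so the target is met in expectation; the
#' per-case realized fraction varies with the sampled radii and
#' rasterization.
#'
#' @param volume_shape integer triple, each >= 16.
#' @param voxel_size_mm positive scalar (isotropic voxels).
#' @param n_stable_lesions non-negative integer count of lesions present at
#'   both timepoints.
#' @param n_new_lesions non-negative integer, or `NULL` to derive it from
#'   `target_positive_fraction`.
#' @param new_lesion_radius_range_mm `(min, max)` lesion radii in mm.
#' @param lesion_contrast lesion intensity offset in units of the background
#'   SD.
#' @param noise_sd per-timepoint additive Gaussian noise SD (intensity
#'   units; the background mean is 1 and its texture SD is 0.1).
#' @param target_positive_fraction desired expected positive-voxel fraction
#'   in `[0, 1)`, or `NULL`.
#' @param seed integer master seed; per-case seeds are derived with
#'   [derive_seed()].
#' @return an object of class `sim_params`.
#' @export
sim_params <- function(volume_shape = c(128L, 128L, 128L),
                       voxel_size_mm = 1,
                       n_stable_lesions = 3L,
                       n_new_lesions = NULL,
                       new_lesion_radius_range_mm = c(1.5, 4),
                       lesion_contrast = 4,
                       noise_sd = 0.05,
                       target_positive_fraction = NULL,
                       seed = 0L) {
  if (is.null(n_new_lesions) && is.null(target_positive_fraction))
    target_positive_fraction <- 5e-5
  volume_shape <- as.integer(volume_shape)
  if (length(volume_shape) != 3L || any(volume_shape < 16L))
    stopf("sim_params: volume_shape must be 3 integers >= 16")
  if (voxel_size_mm <= 0) stopf("sim_params: voxel_size_mm must be > 0")
  rr <- as.double(new_lesion_radius_range_mm)
  if (length(rr) != 2L || any(rr <= 0) || rr[1] > rr[2])
    stopf("sim_params: radius range must satisfy 0 < min <= max")
  if (!is.null(target_positive_fraction) &&
      (target_positive_fraction < 0 || target_positive_fraction >= 1))
    stopf("sim_params: target_positive_fraction must be in [0, 1)")
  if (noise_sd < 0) stopf("sim_params: noise_sd must be >= 0")
  if (lesion_contrast <= 0) stopf("sim_params: lesion_contrast must be > 0")
  p <- list(volume_shape = volume_shape,
            voxel_size_mm = as.double(voxel_size_mm),
            n_stable_lesions = as.integer(n_stable_lesions),
            n_new_lesions = if (is.null(n_new_lesions)) NULL
                            else as.integer(n_new_lesions),
            new_lesion_radius_range_mm = rr,
            lesion_contrast = as.double(lesion_contrast),
            noise_sd = as.double(noise_sd),
            target_positive_fraction = target_positive_fraction,
            seed = as.integer(seed))
  class(p) <- "sim_params"
  p
}

# Expected rasterized sphere volume (in voxels) for r ~ U(a, b):
# (4/3) pi E[r^3] / voxel volume, E[r^3] = (b^4 - a^4) / (4 (b - a)).
expected_sphere_voxels <- function(radius_range_mm, voxel_size_mm) {
  a <- radius_range_mm[1]; b <- radius_range_mm[2]
  er3 <- if (b > a) (b^4 - a^4) / (4 * (b - a)) else a^3
  (4 / 3) * pi * er3 / voxel_size_mm^3
}

resolve_n_new <- function(params) {
  if (!is.null(params$target_positive_fraction)) {
    if (params$target_positive_fraction == 0) return(0L)
    v <- expected_sphere_voxels(params$new_lesion_radius_range_mm,
                                params$voxel_size_mm)
    n <- round(params$target_positive_fraction *
                 prod(params$volume_shape) / v)
    return(max(1L, as.integer(n)))
  }
  params$n_new_lesions
}

# Smooth random field: white noise convolved with a Gaussian kernel
# (sigma in voxels) via FFT, standardized to zero mean / unit SD.
smooth_field <- function(shape, sigma = 4) {
  g <- array(rnorm(prod(shape)), dim = shape)
  ax <- lapply(shape, function(n) {
    f <- c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1)[1:n] / n
    exp(-2 * pi^2 * sigma^2 * f^2)
  })
  ker <- outer(outer(ax[[1]], ax[[2]]), ax[[3]])
  dim(ker) <- shape
  sm <- Re(fft(fft(g) * ker, inverse = TRUE)) / prod(shape)
  (sm - mean(sm)) / sd(as.vector(sm))
}

# Radial intensity profile: 1 inside 0.7 r, tapering linearly through 0.5 at
# the lesion boundary (u = 1) down to 0 at u = 1.3. The ground-truth mask is
# u <= 1, so every mask voxel carries at least half the nominal contrast.
lesion_profile <- function(u) {
  pmin(1, pmax(0, 0.5 + 0.5 * (1 - u) / 0.3))
}

place_lesions <- function(n, radius_range_vox, semi, centers0, radii0,
                          max_tries = 400L) {
  centers <- centers0; radii <- radii0
  out_c <- matrix(0, nrow = n, ncol = 3)
  out_r <- numeric(n)
  ctr <- (semi$shape + 1) / 2
  for (i in seq_len(n)) {
    r <- runif(1, radius_range_vox[1], radius_range_vox[2])
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      # uniform in the shrunken ellipsoid that keeps the lesion inside the
      # brain with a 2-voxel margin
      sa <- semi$ax - r - 2
      if (any(sa <= 1))
        stopf("generate_case: volume too small for a %.1f-voxel lesion", r)
      u <- runif(3, -1, 1)
      if (sum(u^2) > 1) next
      cand <- ctr + u * sa
      ok <- TRUE
      if (length(radii) > 0) {
        dd <- sqrt(colSums((t(centers) - cand)^2))
        ok <- all(dd > radii + r + 2)
      }
      if (ok) {
        centers <- rbind(centers, cand)
        radii <- c(radii, r)
        out_c[i, ] <- cand
        out_r[i] <- r
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stopf("generate_case: could not place lesion %d without overlap; volume too small for the requested lesion load", i)
  }
  list(centers = out_c, radii = out_r,
       all_centers = centers, all_radii = radii)
}

add_lesion <- function(img, center, radius_vox, amplitude, mask = NULL) {
  shp <- dim(img)
  lo <- pmax(1, floor(center - 1.3 * radius_vox - 1))
  hi <- pmin(shp, ceiling(center + 1.3 * radius_vox + 1))
  dx <- (lo[1]:hi[1]) - center[1]
  dy <- (lo[2]:hi[2]) - center[2]
  dz <- (lo[3]:hi[3]) - center[3]
  d2 <- outer(outer(dx^2, dy^2, `+`), dz^2, `+`)
  u <- sqrt(d2) / radius_vox
  img[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <-
    img[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] +
    amplitude * lesion_profile(u)
  if (!is.null(mask)) {
    mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <-
      pmax(mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]], (u <= 1) * 1)
    return(list(img = img, mask = mask))
  }
  list(img = img, mask = NULL)
}

#' Generate one synthetic longitudinal case
#'
#' Builds an ellipsoidal brain region with smooth random texture (identical
#' at both timepoints), adds stable lesions to both images and new lesions
#' to the follow-up only, then adds independent per-timepoint noise. The
#' ground-truth mask marks exactly the new-lesion voxels.
#'
#' @param params a [sim_params()].
#' @param case_index non-negative integer; the per-case seed is
#'   `derive_seed(params$seed, case_index)`, so cases are independent and
#'   reproducible.
#' @return an object of class `longitudinal_case`: fields `baseline`,
#'   `followup`, `gt_mask` ([volume3d()]s on the same grid), `patient_id`,
#'   `case_seed`.
#' @export
generate_case <- function(params, case_index = 0L) {
  stopifnot(inherits(params, "sim_params"))
  case_seed <- derive_seed(params$seed, case_index)
  set.seed(case_seed)
  shp <- params$volume_shape
  vox <- params$voxel_size_mm

  semi <- list(shape = shp, ax = 0.45 * shp)
  ctr <- (shp + 1) / 2
  ex <- ((seq_len(shp[1]) - ctr[1]) / semi$ax[1])^2
  ey <- ((seq_len(shp[2]) - ctr[2]) / semi$ax[2])^2
  ez <- ((seq_len(shp[3]) - ctr[3]) / semi$ax[3])^2
  brain <- outer(outer(ex, ey, `+`), ez, `+`) <= 1

  tex <- smooth_field(shp, sigma = 4)
  bg <- array(0, dim = shp)
  bg[brain] <- 1 + 0.1 * tex[brain]
  sd_bg <- sd(bg[brain])

  n_new <- resolve_n_new(params)
  rr_vox <- params$new_lesion_radius_range_mm / vox
  max_r <- if (n_new > 0 || params$n_stable_lesions > 0) rr_vox[2] else 0
  if (max_r > 0 && any(0.45 * shp - max_r - 2 <= 1))
    stopf("generate_case: volume_shape %s too small to contain %.1f mm lesions",
          paste(shp, collapse = "x"), params$new_lesion_radius_range_mm[2])

  stable <- place_lesions(params$n_stable_lesions, rr_vox, semi,
                          matrix(0, 0, 3), numeric(0))
  newles <- place_lesions(n_new, rr_vox, semi,
                          stable$all_centers, stable$all_radii)

  amp <- params$lesion_contrast * sd_bg
  base_img <- bg
  for (i in seq_len(params$n_stable_lesions)) {
    base_img <- add_lesion(base_img, stable$centers[i, ], stable$radii[i],
                           amp)$img
  }
  fu_img <- base_img
  gt <- array(0, dim = shp)
  for (i in seq_len(n_new)) {
    res <- add_lesion(fu_img, newles$centers[i, ], newles$radii[i], amp,
                      mask = gt)
    fu_img <- res$img
    gt <- res$mask
  }

  if (params$noise_sd > 0) {
    base_img <- base_img + array(rnorm(prod(shp), sd = params$noise_sd), shp)
    fu_img <- fu_img + array(rnorm(prod(shp), sd = params$noise_sd), shp)
  }

  structure(list(
    baseline = volume3d(base_img, vox),
    followup = volume3d(fu_img, vox),
    gt_mask = volume3d(gt, vox),
    patient_id = sprintf("case%03d", case_index),
    case_seed = case_seed
  ), class = "longitudinal_case")
}

#' @export
print.longitudinal_case <- function(x, ...) {
  d <- dim(x$baseline$data)
  cat(sprintf("<longitudinal_case> %s: %d x %d x %d, %d new-lesion voxels (%.3g%% positive)\n",
              x$patient_id, d[1], d[2], d[3], sum(x$gt_mask$data),
              100 * mean(x$gt_mask$data)))
  invisible(x)
}

#' Positive-voxel fraction of a case
#' @param case a `longitudinal_case`.
#' @return fraction of ground-truth-positive voxels in `[0, 1]`.
#' @export
positive_fraction <- function(case) mean(case$gt_mask$data)

#' Generate a dataset of synthetic cases on disk
#'
#' Writes per-case NIfTI triplets (`<id>_baseline.nii.gz`,
#' `<id>_followup.nii.gz`, `<id>_gt.nii.gz`) with the voxel size encoded in
#' the header, plus a JSON `manifest.json` listing the generating
#' parameters and, per case, the patient id, file paths, derived seed and
#' realized positive-voxel fraction.
#'
#' @param params a [sim_params()].
#' @param n_cases positive integer.
#' @param out_dir output directory (created if needed).
#' @return the manifest, invisibly (also written to
#'   `file.path(out_dir, "manifest.json")`).
#' @export
generate_dataset <- function(params, n_cases, out_dir) {
  stopifnot(inherits(params, "sim_params"))
  if (n_cases < 1) stopf("generate_dataset: n_cases must be >= 1")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir))
    stopf("generate_dataset: cannot create directory %s", out_dir)
  cases <- vector("list", n_cases)
  for (i in seq_len(n_cases)) {
    cs <- generate_case(params, i - 1L)
    paths <- file.path(out_dir, paste0(cs$patient_id,
                                       c("_baseline.nii.gz",
                                         "_followup.nii.gz",
                                         "_gt.nii.gz")))
    write_volume(cs$baseline, paths[1])
    write_volume(cs$followup, paths[2])
    write_volume(cs$gt_mask, paths[3])
    cases[[i]] <- list(patient_id = cs$patient_id,
                       baseline = basename(paths[1]),
                       followup = basename(paths[2]),
                       gt = basename(paths[3]),
                       seed = cs$case_seed,
                       positive_fraction = positive_fraction(cs))
  }
  manifest <- list(params = unclass(params), n_cases = n_cases,
                   cases = cases)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(manifest)
}

#' Load a dataset written by [generate_dataset()]
#'
#' @param dir directory containing `manifest.json`.
#' @return list of `longitudinal_case` objects.
#' @export
load_dataset <- function(dir) {
  mf_path <- file.path(dir, "manifest.json")
  if (!file.exists(mf_path)) stopf("load_dataset: no manifest at %s", mf_path)
  mf <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  cases <- mf$cases
  lapply(seq_len(nrow(cases)), function(i) {
    gt <- read_volume(file.path(dir, cases$gt[i]))
    gt$data <- (gt$data > 0.5) * 1
    structure(list(
      baseline = read_volume(file.path(dir, cases$baseline[i])),
      followup = read_volume(file.path(dir, cases$followup[i])),
      gt_mask = gt,
      patient_id = cases$patient_id[i],
      case_seed = cases$seed[i]
    ), class = "longitudinal_case")
  })
}
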