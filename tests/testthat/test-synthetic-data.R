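test_that("a case without new lesions has an empty mask and noise-only change", {
  p <- sim_params(volume_shape = c(32L, 32L, 32L), n_stable_lesions = 2L,
                  n_new_lesions = 0L, noise_sd = 0.05, seed = 1L)
  cs <- generate_case(p, 0L)
  expect_true(all(cs$gt_mask$data == 0))
  d <- cs$followup$data - cs$baseline$data
  # difference is i.i.d. noise from both timepoints: SD ~ sqrt(2) * noise_sd
  expect_lt(abs(sd(as.vector(d)) - sqrt(2) * 0.05), 0.01)
  expect_lt(abs(mean(d)), 0.005)
})

test_that("a 3 mm lesion rasterizes to about the analytic sphere volume", {
  p <- sim_params(volume_shape = c(48L, 48L, 48L), voxel_size_mm = 1,
                  n_stable_lesions = 0L, n_new_lesions = 1L,
                  new_lesion_radius_range_mm = c(3, 3), seed = 2L)
  vol_analytic <- 4 / 3 * pi * 3^3  # ~113 voxels at 1 mm
  for (i in 0:4) {
    cs <- generate_case(p, i)
    expect_gt(sum(cs$gt_mask$data), 0.7 * vol_analytic)
    expect_lt(sum(cs$gt_mask$data), 1.3 * vol_analytic)
  }
})

test_that("generation is deterministic and case-index dependent", {
  p <- sim_params(volume_shape = c(32L, 32L, 32L), n_new_lesions = 1L,
                  n_stable_lesions = 1L, seed = 11L)
  a <- generate_case(p, 3L)
  b <- generate_case(p, 3L)
  expect_identical(a$baseline$data, b$baseline$data)
  expect_identical(a$followup$data, b$followup$data)
  expect_identical(a$gt_mask$data, b$gt_mask$data)
  other <- generate_case(p, 4L)
  expect_false(identical(a$gt_mask$data, other$gt_mask$data))
})

test_that("new lesions are hyperintense at follow-up only; stable lesions stay out of the mask", {
  p <- sim_params(volume_shape = c(48L, 48L, 48L), n_stable_lesions = 2L,
                  n_new_lesions = 2L, new_lesion_radius_range_mm = c(2.5, 3.5),
                  lesion_contrast = 4, noise_sd = 0.05, seed = 3L)
  cs <- generate_case(p, 0L)
  gt <- cs$gt_mask$data == 1
  diff <- mean(cs$followup$data[gt]) - mean(cs$baseline$data[gt])
  # contrast is in background-SD units; the textured background has SD ~ 0.1
  bg_sd <- sd(cs$baseline$data[cs$baseline$data > 0.5 &
                               cs$baseline$data < 1.3])
  expect_gt(diff, p$lesion_contrast / 2 * bg_sd)
  # stable lesions (hyperintense in BOTH images) contribute nothing to gt:
  # strong baseline hyperintensities must be outside the mask
  bright_base <- cs$baseline$data > 1.5
  expect_equal(sum(bright_base & gt), 0)
})

test_that("positive fraction grows with the number of new lesions", {
  frac_for <- function(n_new) {
    p <- sim_params(volume_shape = c(48L, 48L, 48L), n_stable_lesions = 0L,
                    n_new_lesions = n_new,
                    new_lesion_radius_range_mm = c(1.5, 2.5), seed = 17L)
    mean(vapply(0:19, function(i) positive_fraction(generate_case(p, i)),
                numeric(1)))
  }
  f1 <- frac_for(1L); f3 <- frac_for(3L); f6 <- frac_for(6L)
  expect_lte(f1, f3)
  expect_lte(f3, f6)
})

test_that("volumes too small for the requested lesions are rejected", {
  p <- sim_params(volume_shape = c(16L, 16L, 16L), n_new_lesions = 1L,
                  new_lesion_radius_range_mm = c(6, 6), seed = 0L)
  expect_error(generate_case(p, 0L), "small")
  expect_error(sim_params(volume_shape = c(8L, 8L, 8L)), ">= 16")
})

test_that("generate_dataset writes NIfTI triplets plus a manifest that round-trips", {
  dir <- withr::local_tempdir()
  p <- sim_params(volume_shape = c(24L, 24L, 24L), n_stable_lesions = 0L,
                  n_new_lesions = 1L, new_lesion_radius_range_mm = c(2, 3),
                  seed = 9L)
  mf <- generate_dataset(p, 3L, dir)
  expect_length(list.files(dir, pattern = "nii.gz$"), 9L)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  expect_length(mf$cases, 3L)
  expect_equal(vapply(mf$cases, `[[`, "", "patient_id"),
               c("case000", "case001", "case002"))

  cases <- load_dataset(dir)
  mem <- generate_case(p, 1L)
  expect_equal(cases[[2]]$followup$data, mem$followup$data,
               tolerance = 1e-6)
  expect_identical(cases[[2]]$gt_mask$data, mem$gt_mask$data)
  # different case indices place lesions differently
  expect_false(identical(cases[[1]]$gt_mask$data, cases[[3]]$gt_mask$data))
})
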