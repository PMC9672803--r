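test_that("the inference grid enumerates edge-clamped starts", {
  # axis 64: starts 1, 25, 33 (the stride start 49 clamps to 33)
  g <- build_patch_grid(c(64L, 64L, 64L), patch = 32L, stride = 24L)
  expect_equal(sort(unique(g[, 1])), c(1L, 25L, 33L))
  expect_equal(nrow(g), 27L)

  # single-patch axis
  g1 <- build_patch_grid(c(32L, 40L, 48L), patch = 32L, stride = 24L)
  expect_equal(sort(unique(g1[, 1])), 1L)

  # stride-aligned axis 80: consecutive patches overlap by exactly 8
  g2 <- build_patch_grid(c(80L, 80L, 80L), patch = 32L, stride = 24L)
  s <- sort(unique(g2[, 1]))
  expect_equal(s, c(1L, 25L, 49L))
  expect_equal(32L - diff(s), c(8L, 8L))

  expect_error(build_patch_grid(c(16L, 64L, 64L), patch = 32L), "pad")
})

test_that("every voxel is covered by at least one grid patch", {
  set.seed(42)
  for (rep in 1:5) {
    shape <- sample(32:70, 3L, replace = TRUE)
    g <- build_patch_grid(shape, patch = 32L, stride = 24L)
    cov <- array(0L, dim = shape)
    for (i in seq_len(nrow(g))) {
      s <- g[i, ]; e <- s + 31L
      expect_true(all(e <= shape))
      cov[s[1]:e[1], s[2]:e[2], s[3]:e[3]] <-
        cov[s[1]:e[1], s[2]:e[2], s[3]:e[3]] + 1L
    }
    expect_true(all(cov >= 1L))
  }
})

test_that("positive-voxel indexing counts and validates", {
  m <- array(0, c(10, 10, 10))
  expect_equal(nrow(index_positive_patches(m)), 0L)
  m[5, 5, 5] <- 1
  idx <- index_positive_patches(m)
  expect_equal(nrow(idx), 1L)
  expect_equal(as.integer(idx[1, ]), c(5L, 5L, 5L))
  set.seed(2)
  m[sample(1000, 50)] <- 1
  expect_equal(nrow(index_positive_patches(m)), sum(m))
  m[1] <- 0.5
  expect_error(index_positive_patches(m), "binary")
})

test_that("forced-positive sampling places the voxel inside valid starts", {
  gt <- array(0, c(64, 64, 64))
  gt[33, 33, 33] <- 1  # volume center
  x <- array(0, c(64, 64, 64, 2))
  pc <- list(patient_id = "p", x = x, gt = gt,
             pos = index_positive_patches(gt), shape = c(64L, 64L, 64L),
             voxel_size_mm = rep(1, 3))
  set.seed(1)
  for (i in 1:500) {
    r <- sample_positive_patch(pc, patch = 32L)
    expect_true(all(r$start >= 2L & r$start <= 33L))
    expect_true(all(r$start <= 33L & r$start + 31L >= 33L))
    expect_true(r$is_positive)
  }
  pc$pos <- matrix(integer(0), 0, 3)
  expect_error(sample_positive_patch(pc, 32L), "no positive")
})

test_that("sampled patches always contain a positive voxel", {
  cases <- lapply(tiny_cases(2), lesionminer:::prepare_case)
  set.seed(3)
  for (i in 1:2000) {
    ci <- sample(1:2, 1)
    r <- sample_positive_patch(cases[[ci]], patch = 16L)
    expect_true(lesionminer:::patch_contains_positive(cases[[ci]], r$start, 16L))
  }
})

test_that("mining batches contain floor(0.3 * 128) = 38 forced positives", {
  cases <- lapply(tiny_cases(3), lesionminer:::prepare_case)
  cfg <- sampler_config(patch_size = 16L)
  set.seed(4)
  refs <- compose_mining_batch(cfg, cases)
  expect_length(refs, 128L)
  forced <- vapply(refs[1:38], `[[`, logical(1), "is_positive")
  expect_true(all(forced))

  cfg0 <- sampler_config(patch_size = 16L, positive_fraction = 0)
  refs0 <- compose_mining_batch(cfg0, cases)
  expect_length(refs0, 128L)

  cfg1 <- sampler_config(patch_size = 16L, positive_fraction = 1)
  refs1 <- compose_mining_batch(cfg1, cases)
  expect_true(all(vapply(refs1, `[[`, logical(1), "is_positive")))

  empty <- cases[[1]]
  empty$gt <- array(0, dim = empty$shape)
  empty$pos <- matrix(integer(0), 0, 3)
  expect_warning(compose_mining_batch(cfg, list(empty)), "all-uniform")
})

test_that("oversampling reduces to uniform at p = 0 and is all-positive at p = 1", {
  cases <- lapply(tiny_cases(1), lesionminer:::prepare_case)
  # p = 0: chi-square GOF on the start positions of axis 1 (9 valid starts)
  cfg0 <- sampler_config(patch_size = 16L, oversample_p = 0,
                         train_batch_size = 32L)
  set.seed(5)
  starts <- integer(0)
  for (b in 1:150) {
    refs <- sample_oversampled_batch(cfg0, cases)
    starts <- c(starts, vapply(refs, function(r) r$start[1], integer(1)))
  }
  tab <- tabulate(starts, nbins = 9L)
  pval <- stats::chisq.test(tab)$p.value
  expect_gt(pval, 0.001)

  cfg1 <- sampler_config(patch_size = 16L, oversample_p = 1)
  refs1 <- sample_oversampled_batch(cfg1, cases)
  expect_true(all(vapply(refs1, function(r)
    lesionminer:::patch_contains_positive(cases[[r$case]], r$start, 16L),
    logical(1))))
})

test_that("at p = 0.5 about half of the draws are forced positive", {
  # use a case whose lesion is so small that chance positives are rare
  gt <- array(0, c(48, 48, 48)); gt[24, 24, 24] <- 1
  pc <- list(patient_id = "p", x = array(0, c(48, 48, 48, 2)), gt = gt,
             pos = index_positive_patches(gt), shape = c(48L, 48L, 48L),
             voxel_size_mm = rep(1, 3))
  cfg <- sampler_config(patch_size = 16L, oversample_p = 0.5,
                        train_batch_size = 32L)
  set.seed(6)
  n_pos <- 0L; n_tot <- 0L
  for (b in 1:312) {  # ~10^4 draws
    refs <- sample_oversampled_batch(cfg, list(pc))
    n_pos <- n_pos + sum(vapply(refs, `[[`, logical(1), "is_positive"))
    n_tot <- n_tot + length(refs)
  }
  # forced draws are Binomial(n, 1/2); chance positives add at most
  # (16/33)^3 ~ 0.11 of the uniform half
  frac <- n_pos / n_tot
  sigma <- 0.5 / sqrt(n_tot)
  expect_gt(frac, 0.5 - 3 * sigma)
  expect_lt(frac, 0.5 + 0.06 + 3 * sigma)
})

test_that("sampling is reproducible under a fixed seed", {
  cases <- lapply(tiny_cases(2), lesionminer:::prepare_case)
  cfg <- sampler_config(patch_size = 16L)
  set.seed(7); a <- compose_mining_batch(cfg, cases)
  set.seed(7); b <- compose_mining_batch(cfg, cases)
  expect_identical(a, b)
})
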