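test_that("segmentation error matches closed forms and is permutation invariant", {
  dm <- c(4L, 4L, 4L, 1L, 3L)
  gt <- array(rbinom(prod(dm), 1, 0.3), dm)
  zero <- array(0, dm)
  expect_equal(segmentation_error(zero, gt), rep(log(2), 3),
               tolerance = 1e-12)

  # perfect prediction in the saturated-logit limit
  perfect <- array(ifelse(gt == 1, 40, -40), dm)
  expect_true(all(segmentation_error(perfect, gt) < 1e-12))

  # mean of pointwise terms: shuffling voxels jointly changes nothing
  set.seed(1)
  lg <- array(rnorm(prod(dm)), dm)
  perm <- sample(64L)
  lg2 <- lg; gt2 <- gt
  for (n in 1:3) {
    v <- lg[, , , 1, n]; lg2[, , , 1, n] <- array(v[perm], c(4, 4, 4))
    v <- gt[, , , 1, n]; gt2[, , , 1, n] <- array(v[perm], c(4, 4, 4))
  }
  expect_equal(segmentation_error(lg, gt), segmentation_error(lg2, gt2),
               tolerance = 1e-12)

  expect_error(segmentation_error(lg, lg), "binary")
  expect_error(segmentation_error(lg, gt[, , , , 1:2, drop = FALSE]),
               "mismatch")
})

test_that("hard-example selection is a stable top-B", {
  expect_equal(select_hard_examples(c(0.1, 0.9, 0.5, 0.7), 2L), c(2L, 4L))
  expect_equal(select_hard_examples(rep(1, 5), 2L), c(1L, 2L))
  expect_error(select_hard_examples(c(1, 2), 3L), ">")

  # independent oracle: stable ranking by decreasing error
  oracle <- function(errors, B) which(rank(-errors, ties.method = "first") <= B)
  set.seed(2)
  for (i in 1:200) {
    e <- round(runif(128), 2)  # rounding forces ties
    B <- sample(1:128, 1)
    expect_setequal(select_hard_examples(e, B), oracle(e, B))
  }
  for (len in 1:8) for (B in 1:len) {
    e <- round(runif(len), 1)
    expect_setequal(select_hard_examples(e, B), oracle(e, B))
  }
})

test_that("the EMA update follows its geometric closed form", {
  w <- list(a = 1)
  wbar <- list(a = 0)
  wbar <- ema_update(wbar, w, 0.9)
  wbar <- ema_update(wbar, w, 0.9)
  expect_equal(wbar$a, 0.19, tolerance = 1e-12)

  # |wbar_k - w| = mu^k |wbar_0 - w| for a fixed trainee
  wbar <- list(a = 0)
  for (k in 1:100) wbar <- ema_update(wbar, w, 0.99)
  expect_equal(abs(wbar$a - 1), 0.99^100, tolerance = 1e-9)

  expect_identical(ema_update(list(a = 5), w, 0)$a, 1)
  expect_error(ema_update(list(a = 1), list(b = 1), 0.5), "names")
  expect_error(ema_update(wbar, w, 1), "mu")
})

test_that("the learning-rate schedule decays at 50% and 80% inclusively", {
  cfg <- train_config("oversample", total_iterations = 1000L)
  expect_equal(lr_at(400, cfg), 1e-3)
  expect_equal(lr_at(499, cfg), 1e-3)
  expect_equal(lr_at(500, cfg), 1e-4)
  expect_equal(lr_at(799, cfg), 1e-4)
  expect_equal(lr_at(800, cfg), 1e-5)
  expect_equal(lr_at(900, cfg), 1e-5)
})

test_that("with momentum 0 the miner equals the trainee after every iteration", {
  cases <- lapply(tiny_cases(2), lesionminer:::prepare_case)
  cfg <- train_config("ohem", momentum = 0, total_iterations = 3L,
                      mining_batch_size = 16L, train_batch_size = 4L,
                      patch_size = 8L, val_every = 10L, seed = 1L)
  spec <- tiny_spec(8L)
  state <- init_train_state(spec, cfg)
  set.seed(1)
  for (i in 1:3) {
    state <- ohem_iteration(state, cfg, cases)
    expect_identical(state$miner$params, state$net$params)
  }
  expect_equal(state$t, 3L)
  expect_true(is.finite(state$last_loss))
})

test_that("with positive momentum the miner lags the trainee", {
  cases <- lapply(tiny_cases(2), lesionminer:::prepare_case)
  cfg <- train_config("ohem", momentum = 0.9, total_iterations = 2L,
                      mining_batch_size = 16L, train_batch_size = 4L,
                      patch_size = 8L, val_every = 10L, seed = 1L)
  state <- init_train_state(tiny_spec(8L), cfg)
  w0 <- state$net$params$head_w
  set.seed(1)
  state <- ohem_iteration(state, cfg, cases)
  # after one step: wbar = 0.9 w0 + 0.1 w1
  expect_equal(state$miner$params$head_w,
               0.9 * w0 + 0.1 * state$net$params$head_w, tolerance = 1e-12)
})

test_that("training trajectories are reproducible given the config seed", {
  cases <- tiny_cases(3)
  cfg <- train_config("oversample", oversample_p = 0.5,
                      total_iterations = 3L, train_batch_size = 4L,
                      patch_size = 8L, val_every = 1L, seed = 42L)
  spec <- tiny_spec(8L)
  a <- train(cfg, spec, cases[1:2], cases[3])
  b <- train(cfg, spec, cases[1:2], cases[3])
  expect_identical(a$net$params, b$net$params)
  expect_identical(a$log, b$log)
})

test_that("the learning curve has floor(T/K) + 1 rows including iteration 0", {
  cases <- tiny_cases(2)
  cfg <- train_config("oversample", oversample_p = 0.5,
                      total_iterations = 4L, train_batch_size = 2L,
                      patch_size = 8L, val_every = 2L, seed = 3L)
  st <- train(cfg, tiny_spec(8L), cases[1], cases[2])
  expect_equal(st$log$iteration, c(0L, 2L, 4L))
  expect_equal(nrow(st$log), floor(4 / 2) + 1)

  st0 <- train(train_config("oversample", total_iterations = 0L,
                            patch_size = 8L, val_every = 2L, seed = 3L),
               tiny_spec(8L), cases[1], cases[2])
  expect_equal(st0$log$iteration, 0L)
  expect_equal(st0$t, 0L)
})

test_that("ohem pays a mining forward: work units reflect the extra pass", {
  cases <- tiny_cases(2)
  mk <- function(strategy) {
    cfg <- train_config(strategy, total_iterations = 1L,
                        mining_batch_size = 16L, train_batch_size = 4L,
                        patch_size = 8L, val_every = 5L, seed = 1L)
    train(cfg, tiny_spec(8L), cases[1], list())$log$work_units[1]
  }
  expect_equal(mk("ohem") - mk("oversample"), 16)
})
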