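#' Training configuration
#'
#' Parameters of the two training procedures. `strategy = "ohem"` maintains
#' a mining network (an exponential moving average of the trainee with
#' momentum `momentum`) that scores a mining batch of `mining_batch_size`
#' patches; the `train_batch_size` patches with the highest segmentation
#' error are used for the optimizer step. `strategy = "oversample"` draws
#' `train_batch_size` patches directly, forcing each to be positive with
#' probability `oversample_p`. The comparison arms of interest are momenta
#' 0 / 0.9 / 0.99 and p = 0 (uniform) / 0.1 / 0.5.
#'
#' The learning rate is piecewise constant: `lr_values[1]` for the first
#' half of training, `lr_values[2]` from 50\% to 80\%, `lr_values[3]`
#' afterwards (boundaries inclusive).
#'
#' @param strategy `"ohem"` or `"oversample"`.
#' @param momentum EMA momentum in `[0, 1)` (OHEM only).
#' @param oversample_p forced-positive probability in `[0, 1]`
#'   (oversampling only).
#' @param mining_batch_size,train_batch_size mining and training batch
#'   sizes (defaults 128 and 32).
#' @param positive_fraction forced-positive fraction of the mining batch
#'   (default 0.3).
#' @param total_iterations number of optimizer steps `T`.
#' @param lr_values learning-rate plateau values (default
#'   `c(1e-3, 1e-4, 1e-5)`).
#' @param lr_decay_points fractions of `T` at which the decays happen
#'   (default `c(0.5, 0.8)`).
#' @param loss `"bce"` (default) or `"dice_bce"`.
#' @param patch_size training patch edge (default 32).
#' @param val_every validation cadence in iterations (default 250).
#' @param seed integer seed controlling sampling and initialization.
#' @return an object of class `train_config`.
#' @export
train_config <- function(strategy = c("ohem", "oversample"),
                         momentum = 0.9, oversample_p = 0.5,
                         mining_batch_size = 128L, train_batch_size = 32L,
                         positive_fraction = 0.3,
                         total_iterations = 1000L,
                         lr_values = c(1e-3, 1e-4, 1e-5),
                         lr_decay_points = c(0.5, 0.8),
                         loss = c("bce", "dice_bce"),
                         patch_size = 32L, val_every = 250L, seed = 0L) {
  strategy <- match.arg(strategy)
  loss <- match.arg(loss)
  if (momentum < 0 || momentum >= 1)
    stopf("train_config: momentum must be in [0, 1)")
  if (oversample_p < 0 || oversample_p > 1)
    stopf("train_config: oversample_p must be in [0, 1]")
  if (length(lr_values) != 3L || length(lr_decay_points) != 2L)
    stopf("train_config: expected 3 lr_values and 2 lr_decay_points")
  structure(list(strategy = strategy, momentum = as.double(momentum),
                 oversample_p = as.double(oversample_p),
                 mining_batch_size = as.integer(mining_batch_size),
                 train_batch_size = as.integer(train_batch_size),
                 positive_fraction = as.double(positive_fraction),
                 total_iterations = as.integer(total_iterations),
                 lr_values = as.double(lr_values),
                 lr_decay_points = as.double(lr_decay_points),
                 loss = loss, patch_size = as.integer(patch_size),
                 val_every = as.integer(val_every), seed = as.integer(seed)),
            class = "train_config")
}

as_sampler_config <- function(cfg) {
  sampler_config(patch_size = cfg$patch_size,
                 oversample_p = cfg$oversample_p,
                 mining_batch_size = cfg$mining_batch_size,
                 train_batch_size = cfg$train_batch_size,
                 positive_fraction = cfg$positive_fraction,
                 seed = cfg$seed)
}

loss_fn <- function(cfg) if (cfg$loss == "bce") bce_loss else dice_bce_loss

#' Per-patch segmentation error
#'
#' The error used both as the training loss and as the mining score: the
#' mean voxel-wise binary cross-entropy of the logits against the binary
#' ground truth, one scalar per patch. A constant logit of 0 (probability
#' one half everywhere) gives exactly `log(2)` regardless of the target.
#'
#' @param logits `(D, H, W, 1, N)` logits array.
#' @param gt matching binary target array.
#' @return numeric vector of length `N`.
#' @export
segmentation_error <- function(logits, gt) {
  if (!identical(dim(logits), dim(gt)))
    stopf("segmentation_error: shape mismatch (%s) vs (%s)",
          paste(dim(logits), collapse = ","), paste(dim(gt), collapse = ","))
  if (!all(gt %in% c(0, 1)))
    stopf("segmentation_error: ground truth is not binary")
  dm <- dim(logits)
  n <- dm[length(dm)]
  e <- bce_elements(logits, gt)
  colMeans(matrix(e, length(e) / n, n))
}

#' Select the hardest examples of a batch
#'
#' Returns the indices of the `B` largest errors; ties are broken toward
#' the lower index (stable selection).
#'
#' @param errors numeric vector of per-patch errors.
#' @param B number of patches to keep; must not exceed `length(errors)`.
#' @return integer vector of length `B`.
#' @export
select_hard_examples <- function(errors, B) {
  if (B > length(errors))
    stopf("select_hard_examples: B (%d) > number of errors (%d)",
          B, length(errors))
  order(-errors)[seq_len(B)]
}

#' Exponential-moving-average weight update
#'
#' Updates the mining network toward the trainee:
#' `w_bar <- mu * w_bar + (1 - mu) * w`, element-wise on every parameter.
#' With `mu = 0` the miner becomes an exact copy of the trainee.
#'
#' @param wbar,w networks (or flat parameter lists) with identical
#'   names/shapes.
#' @param mu momentum in `[0, 1)`.
#' @return updated `wbar` (same type as the input).
#' @export
ema_update <- function(wbar, w, mu) {
  if (mu < 0 || mu >= 1) stopf("ema_update: mu must be in [0, 1)")
  pw <- if (inherits(w, "unet")) w$params else w
  pb <- if (inherits(wbar, "unet")) wbar$params else wbar
  if (!identical(names(pb), names(pw)))
    stopf("ema_update: parameter names differ")
  for (nm in names(pb)) pb[[nm]] <- mu * pb[[nm]] + (1 - mu) * pw[[nm]]
  if (inherits(wbar, "unet")) { wbar$params <- pb; wbar } else pb
}

#' Learning rate at iteration t
#'
#' Piecewise-constant schedule over `total_iterations`: the decay
#' boundaries at 50\% and 80\% of the training time are inclusive.
#'
#' @param t 0-based iteration, `0 <= t < T`.
#' @param cfg a [train_config()].
#' @return scalar learning rate.
#' @export
lr_at <- function(t, cfg) {
  frac <- t / cfg$total_iterations
  if (frac >= cfg$lr_decay_points[2]) cfg$lr_values[3]
  else if (frac >= cfg$lr_decay_points[1]) cfg$lr_values[2]
  else cfg$lr_values[1]
}

#' Initialize a training state
#'
#' Builds the trainee network `w` and, for OHEM, the mining network
#' `w_bar` as an exact copy of the initial trainee (so momentum 0
#' corresponds to mining with the current model).
#'
#' @param spec a [unet_spec()].
#' @param cfg a [train_config()].
#' @return an object of class `train_state`.
#' @export
init_train_state <- function(spec, cfg) {
  net <- build_unet(spec, seed = derive_seed(cfg$seed, 0L, salt = 1L))
  structure(list(net = net,
                 miner = if (cfg$strategy == "ohem") net else NULL,
                 opt = adam_init(net$params),
                 t = 0L,
                 log = list(),
                 best = NULL),
            class = "train_state")
}

train_step <- function(state, cfg, batch) {
  fw <- unet_forward(state$net, batch$x, cache = TRUE)
  lf <- loss_fn(cfg)
  lo <- lf(fw$logits, batch$y)
  grads <- unet_backward(state$net, fw$cache, lo$dlogits)
  st <- adam_step(state$net$params, grads, state$opt,
                  lr = lr_at(state$t, cfg))
  state$net$params <- st$params
  state$opt <- st$state
  state$last_loss <- lo$loss
  state
}

#' One OHEM training iteration
#'
#' (1) compose a mining batch of `mining_batch_size` patches (30\%
#' forced-positive); (2) score every patch with the mining network (forward
#' only) and keep the `train_batch_size` with the highest error; (3) one
#' Adam step of the trainee on the kept patches; (4) EMA-update the miner
#' toward the trainee.
#'
#' @param state a `train_state`.
#' @param cfg a [train_config()].
#' @param cases list of prepared cases.
#' @return the updated state (`t` incremented, `last_loss` set).
#' @export
ohem_iteration <- function(state, cfg, cases) {
  refs <- compose_mining_batch(as_sampler_config(cfg), cases)
  mb <- extract_batch(cases, refs, cfg$patch_size)
  logits <- unet_forward(state$miner, mb$x)$logits
  err <- segmentation_error(logits, mb$y)
  sel <- select_hard_examples(err, cfg$train_batch_size)
  batch <- list(x = mb$x[, , , , sel, drop = FALSE],
                y = mb$y[, , , , sel, drop = FALSE])
  state <- train_step(state, cfg, batch)
  state$miner <- ema_update(state$miner, state$net, cfg$momentum)
  state$t <- state$t + 1L
  state
}

#' One fixed-oversampling training iteration
#'
#' Draws `train_batch_size` patches with forced-positive probability
#' `oversample_p` and performs one Adam step; no mining network is
#' maintained.
#'
#' @inheritParams ohem_iteration
#' @return the updated state.
#' @export
oversample_iteration <- function(state, cfg, cases) {
  refs <- sample_oversampled_batch(as_sampler_config(cfg), cases)
  batch <- extract_batch(cases, refs, cfg$patch_size)
  state <- train_step(state, cfg, batch)
  state$t <- state$t + 1L
  state
}

validate_dice <- function(net, val_cases, patch, stride, threshold = 0.5) {
  ds <- vapply(val_cases, function(pc) {
    pm <- predict_volume(net, list(data = pc$x,
                                   voxel_size_mm = pc$voxel_size_mm),
                         patch = patch, stride = stride)
    dice(binarize(pm, threshold)$data, pc$gt)
  }, numeric(1))
  mean(ds)
}

#' Train a network with the configured strategy
#'
#' Runs `total_iterations` of [ohem_iteration()] or
#' [oversample_iteration()] with Adam, evaluating the mean full-volume
#' validation Dice (sliding-window inference, threshold 0.5) every
#' `val_every` iterations (including iteration 0), and keeping the weights
#' of the best validation point.
#'
#' @param cfg a [train_config()].
#' @param spec a [unet_spec()].
#' @param train_cases,val_cases lists of `longitudinal_case`s or prepared
#'   cases (`val_cases` may be empty, disabling the curve's Dice column).
#' @param stride inference stride for validation (default
#'   `patch_size - 8`, mirroring the 32/24 grid).
#' @param verbose print progress.
#' @return a `train_state`; its `log` field is a data.frame with columns
#'   `iteration`, `lr`, `train_loss`, `val_dice`, `work_units` (forward
#'   passes per iteration: OHEM pays an extra mining forward of
#'   `mining_batch_size` patches).
#' @export
train <- function(cfg, spec, train_cases, val_cases = list(),
                  stride = NULL, verbose = FALSE) {
  stopifnot(inherits(cfg, "train_config"), inherits(spec, "unet_spec"))
  if (length(train_cases) == 0L) stopf("train: no training cases")
  if (is.null(stride)) stride <- max(1L, cfg$patch_size - 8L)
  train_cases <- lapply(train_cases, function(cs)
    if (inherits(cs, "longitudinal_case")) prepare_case(cs) else cs)
  val_cases <- lapply(val_cases, function(cs)
    if (inherits(cs, "longitudinal_case")) prepare_case(cs) else cs)
  state <- init_train_state(spec, cfg)
  set.seed(derive_seed(cfg$seed, 1L, salt = 2L))
  # work units: forward-equivalent passes per iteration (batch-size-weighted)
  wu <- if (cfg$strategy == "ohem")
    cfg$mining_batch_size + 3 * cfg$train_batch_size
  else 3 * cfg$train_batch_size
  log_rows <- list()
  record <- function(state, loss_val) {
    vd <- if (length(val_cases)) {
      validate_dice(state$net, val_cases, cfg$patch_size, stride)
    } else NA_real_
    row <- data.frame(iteration = state$t,
                      lr = if (state$t < cfg$total_iterations)
                        lr_at(state$t, cfg) else NA_real_,
                      train_loss = loss_val, val_dice = vd,
                      work_units = wu)
    if (!is.na(vd) &&
        (is.null(state$best) || vd > state$best$val_dice)) {
      state$best <- list(iteration = state$t, val_dice = vd,
                         params = state$net$params)
    }
    list(state = state, row = row)
  }
  r0 <- record(state, NA_real_)
  state <- r0$state
  log_rows[[1L]] <- r0$row
  step_fn <- if (cfg$strategy == "ohem") ohem_iteration else oversample_iteration
  for (t in seq_len(cfg$total_iterations)) {
    state <- step_fn(state, cfg, train_cases)
    if (state$t %% cfg$val_every == 0L) {
      r <- record(state, state$last_loss)
      state <- r$state
      log_rows[[length(log_rows) + 1L]] <- r$row
      msg("iter %d/%d lr %.1e loss %.4f val_dice %s", state$t,
          cfg$total_iterations, r$row$lr %||% NA, r$row$train_loss,
          format(r$row$val_dice, digits = 3), verbose = verbose)
    }
  }
  state$log <- do.call(rbind, log_rows)
  state
}

#' Save / load a network checkpoint
#'
#' The weights are serialized with `saveRDS`; a human-readable sidecar JSON
#' (`<path>.json`) records the spec, seed and iteration for provenance.
#'
#' @param state a `train_state` (or a bare `unet` for `net`).
#' @param path checkpoint path (`.rds`).
#' @param extra named list merged into the sidecar JSON.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(state, path, extra = list()) {
  net <- if (inherits(state, "unet")) state else state$net
  saveRDS(net, path)
  side <- c(list(spec = unclass(net$spec),
                 iteration = if (inherits(state, "train_state")) state$t else NA),
            extra)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)
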