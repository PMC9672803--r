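#' Full-volume sliding-window prediction
#'
#' Splits the stacked two-channel volume into a grid of cubic patches
#' (edge `patch`, stride `stride`, edge-clamped; see
#' [build_patch_grid()]), forwards each patch, converts logits to
#' probabilities with the logistic function, and averages all predictions
#' in overlapping regions (uniform weights). Axes shorter than `patch` are
#' reflect-padded up to `patch` and the padding is cropped from the
#' result.
#'
#' @param net a [build_unet()] network.
#' @param x a `stacked_input` (from [stack_timepoints()] /
#'   [preprocess_case()]), or a list with fields `data` (D x H x W x 2
#'   array) and `voxel_size_mm`.
#' @param patch patch edge (default 32).
#' @param stride grid stride (default 24).
#' @param batch_size patches forwarded per network call.
#' @return an object of class `probability_map`: `data` (D x H x W values
#'   in `[0, 1]`), `coverage_count` (patches covering each voxel, >= 1
#'   everywhere), `voxel_size_mm`.
#' @export
predict_volume <- function(net, x, patch = 32L, stride = 24L,
                           batch_size = 16L) {
  stopifnot(inherits(net, "unet"))
  xd <- x$data
  if (length(dim(xd)) != 4L || dim(xd)[4] != net$spec$in_channels)
    stopf("predict_volume: expected D x H x W x %d input", net$spec$in_channels)
  orig <- dim(xd)[1:3]
  pad <- pmax(0L, patch - orig)
  if (any(pad > 0L)) xd <- reflect_pad4(xd, pad)
  shp <- dim(xd)[1:3]
  grid <- build_patch_grid(shp, patch, stride)
  prob <- array(0, dim = shp)
  count <- array(0L, dim = shp)
  nb <- nrow(grid)
  for (i0 in seq.int(1L, nb, by = batch_size)) {
    idx <- i0:min(nb, i0 + batch_size - 1L)
    xb <- array(0, dim = c(patch, patch, patch, dim(xd)[4], length(idx)))
    for (j in seq_along(idx)) {
      s <- grid[idx[j], ]; e <- s + patch - 1L
      xb[, , , , j] <- xd[s[1]:e[1], s[2]:e[2], s[3]:e[3], ]
    }
    pb <- stats::plogis(unet_forward(net, xb)$logits)
    for (j in seq_along(idx)) {
      s <- grid[idx[j], ]; e <- s + patch - 1L
      prob[s[1]:e[1], s[2]:e[2], s[3]:e[3]] <-
        prob[s[1]:e[1], s[2]:e[2], s[3]:e[3]] + pb[, , , 1L, j]
      count[s[1]:e[1], s[2]:e[2], s[3]:e[3]] <-
        count[s[1]:e[1], s[2]:e[2], s[3]:e[3]] + 1L
    }
  }
  prob <- prob / count
  if (any(pad > 0L)) {
    prob <- prob[seq_len(orig[1]), seq_len(orig[2]), seq_len(orig[3]),
                 drop = FALSE]
    count <- count[seq_len(orig[1]), seq_len(orig[2]), seq_len(orig[3]),
                   drop = FALSE]
  }
  structure(list(data = prob, coverage_count = count,
                 voxel_size_mm = x$voxel_size_mm %||% rep(1, 3)),
            class = "probability_map")
}

# Reflect-pad the trailing side of each short spatial axis of a 4D array.
reflect_pad4 <- function(x, pad) {
  d <- dim(x)
  refl <- function(n, p) {
    if (p == 0L) return(seq_len(n))
    # reflect without repeating the edge voxel, falling back to repetition
    # for degenerate single-slice axes
    extra <- if (n > 1L) rev(seq_len(n - 1L))[seq_len(min(p, n - 1L))]
             else integer(0)
    while (length(extra) < p) extra <- c(extra, extra[length(extra)] %||% 1L)
    c(seq_len(n), extra)
  }
  x[refl(d[1], pad[1]), refl(d[2], pad[2]), refl(d[3], pad[3]), ,
    drop = FALSE]
}

#' Binarize a probability map
#'
#' A voxel is positive iff its probability is greater than or equal to the
#' threshold (inclusive comparison).
#'
#' @param pm a `probability_map` (or plain array).
#' @param threshold scalar in `(0, 1)`, default 0.5.
#' @return a binary [volume3d()].
#' @export
binarize <- function(pm, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1)
    stopf("binarize: threshold must be in (0, 1)")
  d <- if (inherits(pm, "probability_map")) pm$data else pm
  vs <- if (inherits(pm, "probability_map")) pm$voxel_size_mm else 1
  volume3d((d >= threshold) * 1, voxel_size_mm = vs)
}
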