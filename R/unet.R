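#' Specification of the 3D UNet
#'
#' A two-level encoder-decoder built from double-convolution blocks
#' `B(n) = 2 x (3x3x3 conv -> group norm -> ReLU)`, max-pool downsampling,
#' trilinear upsampling and a 1x1x1 output head emitting a single logit
#' channel: `B(f1) | pool | B(f2) | pool | B(f3) | up | B(f2) | up | B(f1) | conv(1)`.
#' Skip connections concatenate the encoder feature of matching resolution
#' in front of each decoder block. Probabilities are obtained downstream by
#' applying the logistic function to the logits; the network itself emits
#' logits so losses can be computed in a numerically stable way.
#'
#' @param in_channels input channels (2: baseline + follow-up).
#' @param base_filters filter counts per level, length 3 (default
#'   `c(16, 32, 64)`).
#' @param groups_per_norm groups of each group-normalization layer; must
#'   divide every entry of `base_filters` (default 8).
#' @param patch_size cubic input edge used for training patches; must be
#'   divisible by 4 (two poolings).
#' @param head_bias initial bias of the output head. For heavily imbalanced
#'   targets, initializing it at the prior log-odds of the positive class
#'   (e.g. -3) stops the early iterations from being spent pulling the
#'   background down and speeds up short training runs.
#' @return an object of class `unet_spec`.
#' @export
unet_spec <- function(in_channels = 2L, base_filters = c(16L, 32L, 64L),
                      groups_per_norm = 8L, patch_size = 32L,
                      head_bias = 0) {
  base_filters <- as.integer(base_filters)
  if (length(base_filters) != 3L || any(base_filters < 1L))
    stopf("unet_spec: base_filters must be 3 positive integers")
  if (any(base_filters %% groups_per_norm != 0L))
    stopf("unet_spec: groups_per_norm (%d) must divide all base_filters (%s)",
          groups_per_norm, paste(base_filters, collapse = ", "))
  if (patch_size %% 4L != 0L)
    stopf("unet_spec: patch_size must be divisible by 4 (two pooling levels), got %d",
          patch_size)
  structure(list(in_channels = as.integer(in_channels),
                 base_filters = base_filters,
                 groups_per_norm = as.integer(groups_per_norm),
                 patch_size = as.integer(patch_size),
                 head_bias = as.double(head_bias)),
            class = "unet_spec")
}

# He-uniform initialization for a 3x3x3 conv, stored as the (27*Cin x Cout)
# matrix the GEMM kernel consumes (rows ordered kd, kh, kw, cin).
init_conv <- function(cin, cout) {
  k <- 27L * cin
  lim <- sqrt(6 / k)
  w <- matrix(runif(k * cout, -lim, lim), k, cout)
  attr(w, "cin") <- cin
  w
}

block_param_names <- function(prefix) {
  as.vector(outer(c("conv1_w", "conv1_b", "gn1_gamma", "gn1_beta",
                    "conv2_w", "conv2_b", "gn2_gamma", "gn2_beta"),
                  prefix, function(s, p) paste0(p, "_", s)))
}

init_block <- function(cin, cout) {
  list(conv1_w = init_conv(cin, cout), conv1_b = numeric(cout),
       gn1_gamma = rep(1, cout), gn1_beta = numeric(cout),
       conv2_w = init_conv(cout, cout), conv2_b = numeric(cout),
       gn2_gamma = rep(1, cout), gn2_beta = numeric(cout))
}

#' Build a 3D UNet with deterministic initialization
#'
#' Convolutions use He-uniform initialization; group-norm scales start at 1
#' and offsets at 0. The same `seed` always yields bit-identical weights,
#' and parameter names/shapes depend only on the spec, so two builds from
#' one spec can be combined by an exponential-moving-average update.
#'
#' @param spec a [unet_spec()].
#' @param seed integer seed for the initialization.
#' @return an object of class `unet` with fields `spec` and `params`
#'   (flat named list of parameter arrays).
#' @export
build_unet <- function(spec, seed = 0L) {
  stopifnot(inherits(spec, "unet_spec"))
  set.seed(seed)
  f <- spec$base_filters
  blocks <- list(enc1 = init_block(spec$in_channels, f[1]),
                 enc2 = init_block(f[1], f[2]),
                 bott = init_block(f[2], f[3]),
                 dec2 = init_block(f[3] + f[2], f[2]),
                 dec1 = init_block(f[2] + f[1], f[1]))
  params <- list()
  for (nm in names(blocks))
    for (pn in names(blocks[[nm]]))
      params[[paste0(nm, "_", pn)]] <- blocks[[nm]][[pn]]
  lim <- sqrt(6 / f[1])
  params$head_w <- matrix(runif(f[1], -lim, lim), f[1], 1L)
  params$head_b <- spec$head_bias
  structure(list(spec = spec, params = params), class = "unet")
}

#' @export
print.unet <- function(x, ...) {
  np <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf("<unet> filters (%s), %d input channels, %s parameters\n",
              paste(x$spec$base_filters, collapse = ", "),
              x$spec$in_channels, format(np, big.mark = ",")))
  invisible(x)
}

# ---- layers ---------------------------------------------------------------

gn_eps <- 1e-5

gn_fwd <- function(x, gamma, beta, groups) {
  dm <- dim(x)
  S <- prod(dm[1:3]); C <- dm[4]; N <- dm[5]
  Cg <- C %/% groups
  m <- S * Cg
  xv <- as.vector(x)
  dim(xv) <- c(m, groups * N)
  mu <- colMeans(xv)
  v <- colMeans(xv * xv) - mu * mu
  invstd <- 1 / sqrt(pmax(v, 0) + gn_eps)
  xhat <- (xv - rep(mu, each = m)) * rep(invstd, each = m)
  gam <- rep(rep(gamma, each = S), times = N)
  bet <- rep(rep(beta, each = S), times = N)
  y <- xhat * gam + bet
  dim(y) <- dm
  list(y = y, xhat = xhat, invstd = invstd, dims = dm)
}

gn_bwd <- function(dy, cache, gamma) {
  dm <- cache$dims
  S <- prod(dm[1:3]); C <- dm[4]; N <- dm[5]
  groups <- length(cache$invstd) / N
  Cg <- C / groups
  m <- S * Cg
  dyv <- as.vector(dy)
  xhat <- cache$xhat
  prod_gx <- dyv * as.vector(xhat)
  cs <- colSums(matrix(prod_gx, S, C * N))
  dgamma <- rowSums(matrix(cs, C, N))
  cs2 <- colSums(matrix(dyv, S, C * N))
  dbeta <- rowSums(matrix(cs2, C, N))
  gam <- rep(rep(gamma, each = S), times = N)
  dxhat <- dyv * gam
  dim(dxhat) <- c(m, groups * N)
  mh <- colMeans(dxhat)
  mhx <- colMeans(dxhat * xhat)
  dx <- (dxhat - rep(mh, each = m) - xhat * rep(mhx, each = m)) *
    rep(cache$invstd, each = m)
  dim(dx) <- dm
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

head_fwd <- function(x, w, b) {
  dm <- dim(x)
  S <- prod(dm[1:3]); C <- dm[4]; N <- dm[5]
  y <- array(0, dim = c(dm[1:3], 1L, N))
  for (n in seq_len(N)) {
    xn <- x[, , , , n, drop = FALSE]
    dim(xn) <- c(S, C)
    y[, , , 1L, n] <- xn %*% w + b
  }
  y
}

head_bwd <- function(x, w, dy) {
  dm <- dim(x)
  S <- prod(dm[1:3]); C <- dm[4]; N <- dm[5]
  dx <- array(0, dim = dm)
  dw <- matrix(0, C, 1L)
  db <- 0
  for (n in seq_len(N)) {
    xn <- x[, , , , n, drop = FALSE]; dim(xn) <- c(S, C)
    g <- dy[, , , 1L, n]; dim(g) <- c(S, 1L)
    dw <- dw + crossprod(xn, g)
    db <- db + sum(g)
    dxn <- g %*% t(w)
    dim(dxn) <- c(dm[1:3], C, 1L)
    dx[, , , , n] <- dxn
  }
  list(dx = dx, dw = dw, db = db)
}

concat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, dim = c(da[1:3], da[4] + db[4], da[5]))
  out[, , , seq_len(da[4]), ] <- a
  out[, , , da[4] + seq_len(db[4]), ] <- b
  out
}

block_fwd <- function(params, prefix, x, groups) {
  p <- function(s) params[[paste0(prefix, "_", s)]]
  c1 <- conv3d_fwd_cpp(x, dim(x), p("conv1_w"), p("conv1_b"))
  g1 <- gn_fwd(c1, p("gn1_gamma"), p("gn1_beta"), groups)
  r1 <- g1$y * (g1$y > 0)
  c2 <- conv3d_fwd_cpp(r1, dim(r1), p("conv2_w"), p("conv2_b"))
  g2 <- gn_fwd(c2, p("gn2_gamma"), p("gn2_beta"), groups)
  out <- g2$y * (g2$y > 0)
  list(out = out,
       cache = list(x = x, g1 = g1[c("xhat", "invstd", "dims")],
                    r1 = r1, mask1 = g1$y > 0,
                    g2 = g2[c("xhat", "invstd", "dims")], mask2 = g2$y > 0))
}

block_bwd <- function(params, prefix, cache, dout, groups) {
  p <- function(s) params[[paste0(prefix, "_", s)]]
  grads <- list()
  d <- dout * cache$mask2
  gb2 <- gn_bwd(d, c(cache$g2, list()), p("gn2_gamma"))
  grads[[paste0(prefix, "_gn2_gamma")]] <- gb2$dgamma
  grads[[paste0(prefix, "_gn2_beta")]] <- gb2$dbeta
  cb2 <- conv3d_bwd_cpp(cache$r1, dim(cache$r1), p("conv2_w"), gb2$dx)
  grads[[paste0(prefix, "_conv2_w")]] <- cb2$dw
  grads[[paste0(prefix, "_conv2_b")]] <- cb2$db
  d <- cb2$dx * cache$mask1
  gb1 <- gn_bwd(d, c(cache$g1, list()), p("gn1_gamma"))
  grads[[paste0(prefix, "_gn1_gamma")]] <- gb1$dgamma
  grads[[paste0(prefix, "_gn1_beta")]] <- gb1$dbeta
  cb1 <- conv3d_bwd_cpp(cache$x, dim(cache$x), p("conv1_w"), gb1$dx)
  grads[[paste0(prefix, "_conv1_w")]] <- cb1$dw
  grads[[paste0(prefix, "_conv1_b")]] <- cb1$db
  list(dx = cb1$dx, grads = grads)
}

#' Forward pass of the UNet
#'
#' @param net a [build_unet()] network.
#' @param x numeric 5D array `(D, H, W, C, N)` with `C` matching the spec
#'   and `D, H, W` divisible by 4.
#' @param cache logical; keep the intermediates needed by
#'   [unet_backward()].
#' @return list with `logits` (`(D, H, W, 1, N)` array) and, when
#'   requested, `cache`.
#' @export
unet_forward <- function(net, x, cache = FALSE) {
  stopifnot(inherits(net, "unet"))
  dm <- dim(x)
  if (length(dm) != 5L || dm[4] != net$spec$in_channels)
    stopf("unet_forward: expected (D,H,W,%d,N) input, got (%s)",
          net$spec$in_channels, paste(dm, collapse = ","))
  if (any(dm[1:3] %% 4L != 0L))
    stopf("unet_forward: spatial dims (%s) must be divisible by 4",
          paste(dm[1:3], collapse = ","))
  P <- net$params; G <- net$spec$groups_per_norm
  e1 <- block_fwd(P, "enc1", x, G)
  p1 <- maxpool3d_fwd_cpp(e1$out, dim(e1$out))
  e2 <- block_fwd(P, "enc2", p1$y, G)
  p2 <- maxpool3d_fwd_cpp(e2$out, dim(e2$out))
  bt <- block_fwd(P, "bott", p2$y, G)
  u2 <- upsample2x_fwd_cpp(bt$out, dim(bt$out))
  c2 <- concat_ch(u2, e2$out)
  d2 <- block_fwd(P, "dec2", c2, G)
  u1 <- upsample2x_fwd_cpp(d2$out, dim(d2$out))
  c1 <- concat_ch(u1, e1$out)
  d1 <- block_fwd(P, "dec1", c1, G)
  logits <- head_fwd(d1$out, P$head_w, P$head_b)
  if (!cache) return(list(logits = logits))
  list(logits = logits,
       cache = list(e1 = e1$cache, p1 = p1, e1out_dim = dim(e1$out),
                    e2 = e2$cache, p2 = p2, e2out_dim = dim(e2$out),
                    bt = bt$cache, btout_dim = dim(bt$out),
                    d2 = d2$cache, d2out_dim = dim(d2$out),
                    d1 = d1$cache, d1out = d1$out,
                    c1 = c1, c2 = c2))
}

#' Backward pass of the UNet
#'
#' @param net the network used in the forward pass.
#' @param cache the `cache` element returned by
#'   `unet_forward(..., cache = TRUE)`.
#' @param dlogits gradient of the loss with respect to the logits.
#' @return named list of parameter gradients (same names/shapes as
#'   `net$params`).
#' @export
unet_backward <- function(net, cache, dlogits) {
  P <- net$params; G <- net$spec$groups_per_norm
  f <- net$spec$base_filters
  hb <- head_bwd(cache$d1out, P$head_w, dlogits)
  grads <- list(head_w = hb$dw, head_b = hb$db)
  b1 <- block_bwd(P, "dec1", cache$d1, hb$dx, G)
  grads <- c(grads, b1$grads)
  du1 <- b1$dx[, , , seq_len(f[2]), , drop = FALSE]
  de1_skip <- b1$dx[, , , f[2] + seq_len(f[1]), , drop = FALSE]
  dd2out <- upsample2x_bwd_cpp(du1, cache$d2out_dim)
  b2 <- block_bwd(P, "dec2", cache$d2, dd2out, G)
  grads <- c(grads, b2$grads)
  du2 <- b2$dx[, , , seq_len(f[3]), , drop = FALSE]
  de2_skip <- b2$dx[, , , f[3] + seq_len(f[2]), , drop = FALSE]
  dbtout <- upsample2x_bwd_cpp(du2, cache$btout_dim)
  bb <- block_bwd(P, "bott", cache$bt, dbtout, G)
  grads <- c(grads, bb$grads)
  dp2 <- maxpool3d_bwd_cpp(bb$dx, cache$p2$arg, cache$e2out_dim)
  be2 <- block_bwd(P, "enc2", cache$e2, dp2 + de2_skip, G)
  grads <- c(grads, be2$grads)
  dp1 <- maxpool3d_bwd_cpp(be2$dx, cache$p1$arg, cache$e1out_dim)
  be1 <- block_bwd(P, "enc1", cache$e1, dp1 + de1_skip, G)
  grads <- c(grads, be1$grads)
  grads[names(net$params)]
}

# ---- loss -----------------------------------------------------------------

# Numerically stable elementwise binary cross-entropy on logits:
# max(x, 0) - x y + log(1 + exp(-|x|)).
bce_elements <- function(logits, y) {
  pmax(logits, 0) - logits * y + log1p(exp(-abs(logits)))
}

#' Mean binary cross-entropy loss and its gradient
#'
#' @param logits 5D logits array.
#' @param y matching binary target array.
#' @return list with scalar `loss` and `dlogits` (gradient of the mean
#'   loss).
#' @export
bce_loss <- function(logits, y) {
  n <- length(logits)
  loss <- sum(bce_elements(logits, y)) / n
  dl <- (stats::plogis(logits) - y) / n
  list(loss = loss, dlogits = dl)
}

dice_soft <- function(p, y) {
  num <- 2 * sum(p * y)
  den <- sum(p) + sum(y)
  if (den == 0) return(list(loss = 0, dp = array(0, dim = dim(p))))
  loss <- 1 - num / den
  dp <- (num / den^2) - (2 * y) / den
  list(loss = loss, dp = dp)
}

#' Combined Dice + binary cross-entropy loss
#'
#' Equal-weight sum of the mean BCE and the soft-Dice loss computed on the
#' logistic probabilities.
#' @inheritParams bce_loss
#' @return list with `loss` and `dlogits`.
#' @export
dice_bce_loss <- function(logits, y) {
  b <- bce_loss(logits, y)
  p <- stats::plogis(logits)
  d <- dice_soft(p, y)
  list(loss = b$loss + d$loss,
       dlogits = b$dlogits + d$dp * p * (1 - p))
}

# ---- Adam -----------------------------------------------------------------

adam_init <- function(params) {
  # p * 0 keeps every parameter's exact shape (matrix, vector, scalar)
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
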