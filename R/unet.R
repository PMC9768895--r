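#' U-Net configuration
#'
#' A symmetric encoder-decoder: `depth` contracting stages of two 3x3
#' same-padded convolutions + ReLU followed by 2x2 max-pooling, a two-conv
#' bottleneck, `depth` expanding stages of 2x2 transposed-convolution
#' upsampling, skip concatenation with the matching encoder stage and two
#' 3x3 convolutions + ReLU, and a final 1x1 convolution onto `n_classes`
#' channels. Channel width doubles at each stage from `base_channels`.
#' A network of depth 2 has the canonical 11 convolutional layers
#' (4 + 2 + 4 + 1, not counting the upsampling kernels).
#'
#' @param depth number of down/up stages (>= 1); input spatial dims must be
#'   divisible by `2^depth`.
#' @param base_channels feature channels of the first stage.
#' @param in_channels input image channels (1 for PET slices).
#' @param n_classes output classes (2: background / amyloid-positive).
#' @param seed RNG seed for weight initialization.
#' @return An object of class `unet_config`.
#' @export
unet_config <- function(depth = 2L, base_channels = 8L, in_channels = 1L,
                        n_classes = 2L, seed = 1L) {
  depth <- as.integer(depth); base_channels <- as.integer(base_channels)
  if (depth < 1L) stop("`depth` must be >= 1")
  if (base_channels < 1L) stop("`base_channels` must be >= 1")
  if (n_classes != 2L) stop("this implementation is two-class")
  structure(list(depth = depth, base_channels = base_channels,
                 in_channels = as.integer(in_channels),
                 n_classes = as.integer(n_classes), seed = as.integer(seed)),
            class = "unet_config")
}

# ---- array <-> GEMM layout helpers -----------------------------------------
# Internally feature maps are channel-last [H, W, B, C]: the (i, j, b) block
# is contiguous in memory, so the (H*W*B) x C GEMM view is a zero-copy
# dim() change. The public API (probability maps, logit gradients) uses
# [H, W, C, B]; conversion happens once at the network boundary.

to_mat <- function(X) {
  d <- dim(X)
  dim(X) <- c(d[1] * d[2] * d[3], d[4])
  X
}

from_mat <- function(M, H, W, B, C) {
  dim(M) <- c(H, W, B, C)
  M
}

public_probs <- function(P) aperm(P, c(1, 2, 4, 3))    # [H,W,B,C] -> [H,W,C,B]
internal_probs <- function(P) aperm(P, c(1, 2, 4, 3))  # inverse (2-cycle)

# im2col linear-index cache: gathering the (H*W*B) x (9*C) patch matrix out
# of the zero-padded input is a single subscript operation with these
# indices.
.idx_cache <- new.env(parent = emptyenv())

im2col_idx <- function(H, W, B, C) {
  key <- paste(H, W, B, C, sep = "x")
  hit <- .idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  Hp <- H + 2L; Wp <- W + 2L
  rowpart <- as.vector(outer(outer(0:(H - 1), Hp * (0:(W - 1)), "+"),
                             Hp * Wp * (0:(B - 1)), "+"))
  colpart <- as.vector(outer(outer(0:2, Hp * (0:2), "+"),
                             Hp * Wp * B * (0:(C - 1)), "+"))
  idx <- outer(as.integer(rowpart), as.integer(colpart), "+") + 1L
  storage.mode(idx) <- "integer"
  .idx_cache[[key]] <- idx
  idx
}

pad_zero <- function(X) {
  d <- dim(X)
  Xp <- array(0, c(d[1] + 2L, d[2] + 2L, d[3], d[4]))
  Xp[2:(d[1] + 1), 2:(d[2] + 1), , ] <- X
  Xp
}

im2col <- function(X) {
  d <- dim(X)
  idx <- im2col_idx(d[1], d[2], d[3], d[4])
  M <- pad_zero(X)[idx]
  dim(M) <- dim(idx)
  M
}

# 3x3 same-padded convolution. W is (9*Cin) x Cout with rows ordered
# (di, dj, cin); b has length Cout.
conv_fwd <- function(X, W, b) {
  d <- dim(X)
  M <- im2col(X)
  Y <- M %*% W
  Y <- Y + rep(b, each = nrow(Y))
  list(Y = from_mat(Y, d[1], d[2], d[3], ncol(W)), M = M)
}

# Input gradient of a same-padded conv is itself a same-padded conv of dY
# with the 180-degree-rotated, in/out-transposed kernel: gather + GEMM
# instead of a scatter.
rotate_weights <- function(W, Cin) {
  Cout <- ncol(W)
  Warr <- array(W, c(3L, 3L, Cin, Cout))
  Wr <- aperm(Warr[3:1, 3:1, , , drop = FALSE], c(1, 2, 4, 3))
  dim(Wr) <- c(9L * Cout, Cin)
  Wr
}

conv_bwd <- function(dY, M, W, xdims) {
  C <- xdims[4]
  dYmat <- to_mat(dY)
  dW <- crossprod(M, dYmat)
  db <- colSums(dYmat)
  dM <- im2col(dY)
  dX <- dM %*% rotate_weights(W, C)
  list(dX = from_mat(dX, xdims[1], xdims[2], xdims[3], C),
       dW = dW, db = db)
}

relu <- function(X) { X[X < 0] <- 0; X }

# 2x2 max pooling, stride 2; masks route gradients to the argmax
# (first-wins tie break).
maxpool_fwd <- function(X) {
  d <- dim(X); H <- d[1]; W <- d[2]; B <- d[3]; C <- d[4]
  Xr <- X
  dim(Xr) <- c(2L, H %/% 2L, 2L, W %/% 2L, B, C)
  sub <- function(a, b2) {
    s <- Xr[a, , b2, , , , drop = FALSE]
    dim(s) <- c(H %/% 2L, W %/% 2L, B, C)
    s
  }
  s11 <- sub(1, 1); s21 <- sub(2, 1); s12 <- sub(1, 2); s22 <- sub(2, 2)
  Y <- pmax(s11, s21, s12, s22)
  m11 <- s11 == Y
  m21 <- (s21 == Y) & !m11
  m12 <- (s12 == Y) & !m11 & !m21
  m22 <- (s22 == Y) & !m11 & !m21 & !m12
  list(Y = Y, masks = list(m11, m21, m12, m22), xdims = d)
}

maxpool_bwd <- function(dY, pool) {
  d <- pool$xdims
  dXr <- array(0, c(2L, d[1] %/% 2L, 2L, d[2] %/% 2L, d[3], d[4]))
  put <- function(a, b2, m) dXr[a, , b2, , , ] <<- dY * m
  put(1, 1, pool$masks[[1]]); put(2, 1, pool$masks[[2]])
  put(1, 2, pool$masks[[3]]); put(2, 2, pool$masks[[4]])
  dim(dXr) <- d
  dXr
}

# 2x2 stride-2 transposed convolution (learned upsampling). K is
# [2, 2, Cin, Cout]; each input pixel paints a 2x2 output block.
upconv_fwd <- function(X, K, b) {
  d <- dim(X); h <- d[1]; w <- d[2]; B <- d[3]; Cin <- d[4]
  Cout <- dim(K)[4]
  Xmat <- to_mat(X)
  Y <- array(0, c(2L * h, 2L * w, B, Cout))
  for (a in 1:2) for (bb in 1:2) {
    Kab <- matrix(K[a, bb, , ], Cin, Cout)
    Yab <- Xmat %*% Kab
    Yab <- Yab + rep(b, each = nrow(Yab))
    Y[seq(a, 2L * h, 2L), seq(bb, 2L * w, 2L), , ] <-
      from_mat(Yab, h, w, B, Cout)
  }
  list(Y = Y, Xmat = Xmat, xdims = d)
}

upconv_bwd <- function(dY, up, K) {
  d <- up$xdims; h <- d[1]; w <- d[2]; B <- d[3]; Cin <- d[4]
  Cout <- dim(K)[4]
  dK <- array(0, dim(K)); db <- numeric(Cout)
  dXmat <- matrix(0, nrow(up$Xmat), Cin)
  for (a in 1:2) for (bb in 1:2) {
    dYab <- dY[seq(a, 2L * h, 2L), seq(bb, 2L * w, 2L), , , drop = FALSE]
    dYabm <- to_mat(dYab)
    dK[a, bb, , ] <- crossprod(up$Xmat, dYabm)
    db <- db + colSums(dYabm)
    dXmat <- dXmat + tcrossprod(dYabm, matrix(K[a, bb, , ], Cin, Cout))
  }
  list(dX = from_mat(dXmat, h, w, B, Cin), dK = dK, db = db)
}

# Two-channel softmax over the class dimension of [H, W, B, 2] logits.
softmax2 <- function(L) {
  a1 <- L[, , , 1, drop = FALSE]; a2 <- L[, , , 2, drop = FALSE]
  m <- pmax(a1, a2)
  e1 <- exp(a1 - m); e2 <- exp(a2 - m)
  s <- e1 + e2
  P <- L
  P[, , , 1] <- e1 / s
  P[, , , 2] <- e2 / s
  P
}

# ---- network construction --------------------------------------------------

he_mat <- function(nin, nout, fan_in) {
  matrix(stats::rnorm(nin * nout, 0, sqrt(2 / fan_in)), nin, nout)
}

#' Build a 2D U-Net
#'
#' Allocates and He-initializes all weights (seeded from the config).
#'
#' @param cfg a [unet_config()].
#' @return An object of class `unet`: list with `cfg` and nested `params`.
#' @seealso [unet_forward()], [n_parameters()]
#' @export
build_unet <- function(cfg) {
  stopifnot(inherits(cfg, "unet_config"))
  ch <- function(s) cfg$base_channels * 2L^(s - 1L)
  with_seed(cfg$seed, {
    enc <- lapply(seq_len(cfg$depth), function(s) {
      cin <- if (s == 1L) cfg$in_channels else ch(s - 1L)
      list(conv1 = list(W = he_mat(9L * cin, ch(s), 9L * cin),
                        b = numeric(ch(s))),
           conv2 = list(W = he_mat(9L * ch(s), ch(s), 9L * ch(s)),
                        b = numeric(ch(s))))
    })
    cb <- ch(cfg$depth + 1L)
    bottleneck <- list(
      conv1 = list(W = he_mat(9L * ch(cfg$depth), cb, 9L * ch(cfg$depth)),
                   b = numeric(cb)),
      conv2 = list(W = he_mat(9L * cb, cb, 9L * cb), b = numeric(cb)))
    dec <- lapply(seq_len(cfg$depth), function(s) {
      clow <- if (s == cfg$depth) cb else ch(s + 1L)
      K <- array(stats::rnorm(4L * clow * ch(s), 0, sqrt(2 / clow)),
                 c(2L, 2L, clow, ch(s)))
      list(up = list(K = K, b = numeric(ch(s))),
           conv1 = list(W = he_mat(9L * 2L * ch(s), ch(s), 9L * 2L * ch(s)),
                        b = numeric(ch(s))),
           conv2 = list(W = he_mat(9L * ch(s), ch(s), 9L * ch(s)),
                        b = numeric(ch(s))))
    })
    final <- list(W = he_mat(ch(1L), cfg$n_classes, ch(1L)),
                  b = numeric(cfg$n_classes))
    structure(list(cfg = cfg,
                   params = list(enc = enc, bottleneck = bottleneck,
                                 dec = dec, final = final)),
              class = "unet")
  })
}

#' @export
print.unet <- function(x, ...) {
  cat(sprintf(
    "<unet> depth %d, base %d channels, %d conv layers, %d parameters\n",
    x$cfg$depth, x$cfg$base_channels, conv_layer_count(x$cfg),
    n_parameters(x)))
  invisible(x)
}

#' Number of convolutional layers of a configuration
#'
#' Two per encoder stage, two in the bottleneck, two per decoder stage and
#' the final 1x1 layer: `4 * depth + 3` (11 at depth 2). Upsampling kernels
#' are not counted.
#'
#' @param cfg a [unet_config()].
#' @return Integer count.
#' @export
conv_layer_count <- function(cfg) 4L * cfg$depth + 3L

# ---- parameter flattening (for the optimizer and gradient checks) ----------

flatten_params <- function(x, prefix = "") {
  if (is.numeric(x)) return(stats::setNames(list(x), prefix))
  nms <- names(x)
  if (is.null(nms)) nms <- as.character(seq_along(x))  # stage lists
  out <- list()
  for (i in seq_along(x))
    out <- c(out, flatten_params(
      x[[i]], if (nzchar(prefix)) paste0(prefix, ".", nms[i]) else nms[i]))
  out
}

unflatten_params <- function(template, flat, prefix = "") {
  if (is.numeric(template)) return(flat[[prefix]])
  nms <- names(template)
  if (is.null(nms)) nms <- as.character(seq_along(template))
  for (i in seq_along(template))
    template[[i]] <- unflatten_params(
      template[[i]], flat,
      if (nzchar(prefix)) paste0(prefix, ".", nms[i]) else nms[i])
  template
}

#' Total trainable parameter count
#'
#' @param net a `unet` (or any nested parameter list).
#' @return Integer: sum of the lengths of all weight and bias arrays.
#' @export
n_parameters <- function(net) {
  p <- if (inherits(net, "unet")) net$params else net
  sum(vapply(flatten_params(p), length, integer(1)))
}

# ---- forward / backward ----------------------------------------------------

# Coerce a matrix / list of matrices / public [H,W,C,B] array to the
# internal channel-last batch layout [H,W,B,C].
as_batch <- function(x, in_channels = 1L) {
  if (is.list(x)) {
    H <- nrow(x[[1]]); W <- ncol(x[[1]])
    arr <- array(0, c(H, W, length(x), in_channels))
    for (i in seq_along(x)) arr[, , i, 1] <- x[[i]]
    return(arr)
  }
  if (is.matrix(x)) return(array(x, c(dim(x), 1L, 1L)))
  if (length(dim(x)) == 4L) return(aperm(x, c(1, 2, 4, 3)))
  stop("input must be a matrix, list of matrices, or [H,W,C,B] array")
}

#' U-Net forward pass
#'
#' Runs a batch through the network and applies the two-class softmax, so
#' every pixel carries a probability pair summing to 1.
#'
#' @param net a built [build_unet()] network.
#' @param x input batch: a single `H x W` matrix, a list of matrices, or an
#'   `[H, W, C, B]` array. `H` and `W` must be divisible by `2^depth`.
#' @param training if `TRUE`, intermediate activations are cached for
#'   [unet_backward()].
#' @return list with `probs` (`[H, W, 2, B]` softmax maps), `logits`, and
#'   (when training) `cache`.
#' @export
unet_forward <- function(net, x, training = FALSE) {
  stopifnot(inherits(net, "unet"))
  x <- as_batch(x, net$cfg$in_channels)
  d <- dim(x)
  if (d[4] != net$cfg$in_channels)
    stop(sprintf("expected %d input channel(s), got %d",
                 net$cfg$in_channels, d[4]))
  if (d[1] %% 2L^net$cfg$depth != 0L || d[2] %% 2L^net$cfg$depth != 0L)
    stop(sprintf("spatial dims must be divisible by 2^depth = %d",
                 2L^net$cfg$depth))
  p <- net$params
  cache <- if (training) list(x = x) else NULL

  h <- x; skips <- vector("list", net$cfg$depth)
  enc_c <- vector("list", net$cfg$depth)
  for (s in seq_len(net$cfg$depth)) {
    xdims1 <- dim(h)
    c1 <- conv_fwd(h, p$enc[[s]]$conv1$W, p$enc[[s]]$conv1$b)
    a1 <- relu(c1$Y)
    c2 <- conv_fwd(a1, p$enc[[s]]$conv2$W, p$enc[[s]]$conv2$b)
    a2 <- relu(c2$Y)
    skips[[s]] <- a2
    pool <- maxpool_fwd(a2)
    if (training)
      enc_c[[s]] <- list(M1 = c1$M, a1 = a1, xdims1 = xdims1,
                         M2 = c2$M, a2 = a2, pool = pool)
    h <- pool$Y
  }

  xdims_b1 <- dim(h)
  b1 <- conv_fwd(h, p$bottleneck$conv1$W, p$bottleneck$conv1$b)
  ab1 <- relu(b1$Y)
  b2 <- conv_fwd(ab1, p$bottleneck$conv2$W, p$bottleneck$conv2$b)
  ab2 <- relu(b2$Y)
  if (training)
    cache$bottleneck <- list(M1 = b1$M, a1 = ab1, xdims1 = xdims_b1,
                             M2 = b2$M, a2 = ab2)
  h <- ab2

  dec_c <- vector("list", net$cfg$depth)
  for (s in rev(seq_len(net$cfg$depth))) {
    up <- upconv_fwd(h, p$dec[[s]]$up$K, p$dec[[s]]$up$b)
    ch_up <- dim(up$Y)[4]; ch_skip <- dim(skips[[s]])[4]
    catd <- dim(up$Y); catd[4] <- ch_up + ch_skip
    hcat <- array(0, catd)
    hcat[, , , seq_len(ch_up)] <- up$Y
    hcat[, , , ch_up + seq_len(ch_skip)] <- skips[[s]]
    c1 <- conv_fwd(hcat, p$dec[[s]]$conv1$W, p$dec[[s]]$conv1$b)
    a1 <- relu(c1$Y)
    c2 <- conv_fwd(a1, p$dec[[s]]$conv2$W, p$dec[[s]]$conv2$b)
    a2 <- relu(c2$Y)
    if (training)
      dec_c[[s]] <- list(up = up, ch_up = ch_up, ch_skip = ch_skip,
                         M1 = c1$M, a1 = a1, xdims_cat = catd,
                         M2 = c2$M, a2 = a2)
    h <- a2
  }

  hd <- dim(h)
  Hmat <- to_mat(h)
  logits_mat <- Hmat %*% p$final$W
  logits_mat <- logits_mat + rep(p$final$b, each = nrow(logits_mat))
  logits <- from_mat(logits_mat, hd[1], hd[2], hd[3], net$cfg$n_classes)
  if (training) {
    cache$enc <- enc_c; cache$dec <- dec_c
    cache$final <- list(Hmat = Hmat, hdims = hd)
  }
  list(probs = public_probs(softmax2(logits)),
       logits = public_probs(logits), cache = cache)
}

#' U-Net backward pass
#'
#' Backpropagates a gradient with respect to the logits through the whole
#' network, returning parameter gradients in the same nested layout as
#' `net$params`.
#'
#' @param net the network used in the forward pass.
#' @param cache the `cache` from `unet_forward(..., training = TRUE)`.
#' @param dlogits gradient of the loss w.r.t. the logits, `[H, W, 2, B]`.
#' @return Nested list of gradients.
#' @export
unet_backward <- function(net, cache, dlogits) {
  p <- net$params
  grads <- p  # same shape, overwritten below

  fin <- cache$final
  dYmat <- to_mat(internal_probs(dlogits))
  grads$final$W <- crossprod(fin$Hmat, dYmat)
  grads$final$b <- colSums(dYmat)
  dH <- from_mat(tcrossprod(dYmat, p$final$W),
                 fin$hdims[1], fin$hdims[2], fin$hdims[3], fin$hdims[4])

  dskips <- vector("list", net$cfg$depth)
  for (s in seq_len(net$cfg$depth)) {   # reverse of forward (depth..1)
    dc <- cache$dec[[s]]
    d2 <- dH * (dc$a2 > 0)
    bw2 <- conv_bwd(d2, dc$M2, p$dec[[s]]$conv2$W, dim(dc$a1))
    grads$dec[[s]]$conv2$W <- bw2$dW; grads$dec[[s]]$conv2$b <- bw2$db
    d1 <- bw2$dX * (dc$a1 > 0)
    bw1 <- conv_bwd(d1, dc$M1, p$dec[[s]]$conv1$W, dc$xdims_cat)
    grads$dec[[s]]$conv1$W <- bw1$dW; grads$dec[[s]]$conv1$b <- bw1$db
    dUp <- bw1$dX[, , , seq_len(dc$ch_up), drop = FALSE]
    dskips[[s]] <- bw1$dX[, , , dc$ch_up + seq_len(dc$ch_skip),
                          drop = FALSE]
    bwu <- upconv_bwd(dUp, dc$up, p$dec[[s]]$up$K)
    grads$dec[[s]]$up$K <- bwu$dK; grads$dec[[s]]$up$b <- bwu$db
    dH <- bwu$dX
  }

  bc <- cache$bottleneck
  d2 <- dH * (bc$a2 > 0)
  bw2 <- conv_bwd(d2, bc$M2, p$bottleneck$conv2$W, dim(bc$a1))
  grads$bottleneck$conv2$W <- bw2$dW; grads$bottleneck$conv2$b <- bw2$db
  d1 <- bw2$dX * (bc$a1 > 0)
  bw1 <- conv_bwd(d1, bc$M1, p$bottleneck$conv1$W, bc$xdims1)
  grads$bottleneck$conv1$W <- bw1$dW; grads$bottleneck$conv1$b <- bw1$db
  dH <- bw1$dX

  for (s in rev(seq_len(net$cfg$depth))) {
    ec <- cache$enc[[s]]
    dA2 <- maxpool_bwd(dH, ec$pool) + dskips[[s]]
    d2 <- dA2 * (ec$a2 > 0)
    bw2 <- conv_bwd(d2, ec$M2, p$enc[[s]]$conv2$W, dim(ec$a1))
    grads$enc[[s]]$conv2$W <- bw2$dW; grads$enc[[s]]$conv2$b <- bw2$db
    d1 <- bw2$dX * (ec$a1 > 0)
    bw1 <- conv_bwd(d1, ec$M1, p$enc[[s]]$conv1$W, ec$xdims1)
    grads$enc[[s]]$conv1$W <- bw1$dW; grads$enc[[s]]$conv1$b <- bw1$db
    dH <- bw1$dX
  }
  grads
}

# Batch soft-IoU loss and gradient w.r.t. the foreground probability map.
# Per-image losses are averaged; an empty-vs-empty image contributes loss 0
# and zero gradient (silently -- routine for amyloid-negative slices).
soft_iou_batch <- function(p_fg, g) {
  B <- dim(p_fg)[3]
  loss <- 0
  grad <- array(0, dim(p_fg))
  for (i in seq_len(B)) {
    pi_ <- p_fg[, , i]; gi <- g[, , i]
    inter <- sum(pi_ * gi)
    uni <- sum(pi_) + sum(gi) - inter
    if (!is.finite(uni)) return(list(loss = NaN, grad = grad))
    if (uni == 0) next
    loss <- loss + (1 - inter / uni)
    grad[, , i] <- -(gi * uni - inter * (1 - gi)) / uni^2
  }
  list(loss = loss / B, grad = grad / B)
}

#' Loss and parameter gradients for a batch
#'
#' The training objective: mean per-image soft-IoU loss on the foreground
#' softmax channel, optionally plus `lambda_ce` times the mean pixelwise
#' two-class cross-entropy. The gradient is pushed through the softmax and
#' the whole network analytically.
#'
#' @param net a `unet`.
#' @param x input batch (see [unet_forward()]).
#' @param g binary target masks, `[H, W, B]` array (or matrix/list matching
#'   the batch).
#' @param lambda_ce weight of the auxiliary cross-entropy term (default 0:
#'   pure Jaccard training).
#' @return list with `loss`, `iou_loss`, `ce`, `grads`, `probs`.
#' @export
unet_loss_and_grads <- function(net, x, g, lambda_ce = 0) {
  if (is.matrix(g)) g <- array(g, c(dim(g), 1L))
  if (is.list(g)) {
    garr <- array(0, c(dim(g[[1]]), length(g)))
    for (i in seq_along(g)) garr[, , i] <- g[[i]]
    g <- garr
  }
  fw <- unet_forward(net, x, training = TRUE)
  d <- dim(fw$probs)
  p_fg <- array(fw$probs[, , 2, ], c(d[1], d[2], d[4]))
  p_bg <- array(fw$probs[, , 1, ], c(d[1], d[2], d[4]))

  si <- soft_iou_batch(p_fg, g)
  e <- si$grad
  ce <- 0
  if (lambda_ce > 0) {
    eps <- 1e-12
    pc <- pmin(pmax(p_fg, eps), 1 - eps)
    npx <- d[1] * d[2] * d[4]
    ce <- -sum(g * log(pc) + (1 - g) * log(1 - pc)) / npx
    e <- e + lambda_ce * (-(g / pc) + (1 - g) / (1 - pc)) / npx
  }

  dlog <- array(0, d)
  common <- e * p_fg * p_bg
  dlog[, , 2, ] <- common
  dlog[, , 1, ] <- -common
  grads <- unet_backward(net, fw$cache, dlog)
  list(loss = si$loss + lambda_ce * ce, iou_loss = si$loss, ce = ce,
       grads = grads, probs = fw$probs)
}

#' Predict a probability map for a single slice
#'
#' @param net a trained `unet`.
#' @param image `H x W` matrix.
#' @return `[H, W, 2]` array of class probabilities.
#' @export
unet_predict <- function(net, image) {
  out <- unet_forward(net, image)$probs
  array(out, dim(out)[1:3])
}

#' Save / load a network checkpoint
#'
#' The configuration travels inside the checkpoint, so a loaded network is
#' self-describing.
#'
#' @param net a `unet`.
#' @param path checkpoint file.
#' @return `path` (save) or the restored `unet` (load).
#' @export
save_unet <- function(net, path) {
  stopifnot(inherits(net, "unet"))
  saveRDS(net, path)
  invisible(path)
}

#' @rdname save_unet
#' @export
load_unet <- function(path) {
  net <- readRDS(path)
  stopifnot(inherits(net, "unet"))
  net
}
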