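## Minimal CPU neural-network primitives. Every layer exposes an explicit
## forward returning a cache and a backward consuming it, so the two small
## networks in this package (segmenter, feature extractor) are composed by
## hand and every gradient is checkable by finite differences.
##
## Convolutions use a compiled dilated im2col: the column matrix has one row
## per pixel and 9*Cin columns (tap-major within channel), so a 3x3 conv is
## a single BLAS matmul against a (9*Cin) x Cout weight matrix.

as_img3 <- function(x) {
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  x
}

conv_fwd <- function(x, W, b, rate = 1L) {
  x <- as_img3(x)
  d <- dim(x)
  if (rate >= max(d[1], d[2]))
    stop("dilation rate too large for image size")
  cols <- im2col_dilated(x, d[1], d[2], d[3], as.integer(rate))
  out_m <- cols %*% W
  out_m <- out_m + rep(b, each = nrow(out_m))
  out <- out_m
  dim(out) <- c(d[1], d[2], ncol(W))
  list(out = out, cols = cols, dims = d, rate = as.integer(rate), W = W)
}

conv_bwd <- function(cache, dY) {
  d <- cache$dims
  dY_m <- dY; dim(dY_m) <- c(d[1] * d[2], length(dY) / (d[1] * d[2]))
  dW <- crossprod(cache$cols, dY_m)
  db <- colSums(dY_m)
  dX <- col2im_dilated(dY_m %*% t(cache$W), d[1], d[2], d[3], cache$rate)
  list(dW = dW, db = db, dX = dX)
}

conv1x1_fwd <- function(x, W, b) {
  x <- as_img3(x)
  d <- dim(x)
  xm <- x; dim(xm) <- c(d[1] * d[2], d[3])
  out_m <- xm %*% W + rep(b, each = d[1] * d[2])
  out <- out_m; dim(out) <- c(d[1], d[2], ncol(W))
  list(out = out, xm = xm, dims = d, W = W)
}

conv1x1_bwd <- function(cache, dY) {
  d <- cache$dims
  dY_m <- dY; dim(dY_m) <- c(d[1] * d[2], length(dY) / (d[1] * d[2]))
  dX <- dY_m %*% t(cache$W)
  dim(dX) <- d
  list(dW = crossprod(cache$xm, dY_m), db = colSums(dY_m), dX = dX)
}

relu_fwd <- function(x) list(out = pmax(x, 0), mask = x > 0)
relu_bwd <- function(cache, dY) dY * cache$mask

# Instance normalization (per image, per channel over spatial positions),
# without affine parameters. Deterministic at train and test time.
inorm_fwd <- function(x, eps = 1e-5) {
  x <- as_img3(x)
  d <- dim(x); n <- d[1] * d[2]
  xm <- x; dim(xm) <- c(n, d[3])
  mu <- colMeans(xm)
  xc <- xm - rep(mu, each = n)
  v <- colMeans(xc^2)
  s <- sqrt(v + eps)
  xhat <- xc / rep(s, each = n)
  out <- xhat; dim(out) <- d
  list(out = out, xhat = xhat, s = s, dims = d)
}

inorm_bwd <- function(cache, dY) {
  d <- cache$dims; n <- d[1] * d[2]
  dy <- dY; dim(dy) <- c(n, d[3])
  m1 <- colMeans(dy)
  m2 <- colMeans(dy * cache$xhat)
  dx <- (dy - rep(m1, each = n) - cache$xhat * rep(m2, each = n)) /
    rep(cache$s, each = n)
  dim(dx) <- d
  dx
}

down2_fwd <- function(x) {
  x <- as_img3(x)
  d <- dim(x)
  iy <- seq(1, d[1], by = 2); ix <- seq(1, d[2], by = 2)
  list(out = x[iy, ix, , drop = FALSE], dims = d, iy = iy, ix = ix)
}

down2_bwd <- function(cache, dY) {
  dX <- array(0, cache$dims)
  dX[cache$iy, cache$ix, ] <- dY
  dX
}

# Bilinear interpolation matrix mapping n_in samples to n_out (half-pixel
# centers, edges clamped). Upsampling is out = A %*% x %*% t(B) per channel.
interp_matrix <- function(n_out, n_in) {
  A <- matrix(0, n_out, n_in)
  src <- (seq_len(n_out) - 0.5) * n_in / n_out + 0.5
  lo <- pmin(pmax(floor(src), 1), n_in)
  hi <- pmin(lo + 1, n_in)
  f <- pmin(pmax(src - lo, 0), 1)
  for (i in seq_len(n_out)) {
    A[i, lo[i]] <- A[i, lo[i]] + (1 - f[i])
    A[i, hi[i]] <- A[i, hi[i]] + f[i]
  }
  A
}

upsample_fwd <- function(x, A, B) {
  x <- as_img3(x)
  d <- dim(x)
  out <- array(0, c(nrow(A), nrow(B), d[3]))
  for (c in seq_len(d[3])) out[, , c] <- A %*% x[, , c] %*% t(B)
  list(out = out, A = A, B = B, dims = d)
}

upsample_bwd <- function(cache, dY) {
  dX <- array(0, cache$dims)
  for (c in seq_len(cache$dims[3]))
    dX[, , c] <- t(cache$A) %*% dY[, , c] %*% cache$B
  dX
}

gap_fwd <- function(x) {
  x <- as_img3(x)
  d <- dim(x)
  xm <- x; dim(xm) <- c(d[1] * d[2], d[3])
  list(out = colMeans(xm), dims = d)
}

gap_bwd <- function(cache, dY) {
  d <- cache$dims
  dX <- array(rep(dY / (d[1] * d[2]), each = d[1] * d[2]), d)
  dX
}

linear_fwd <- function(x, W, b) list(out = as.numeric(x %*% W + b), x = x, W = W)
linear_bwd <- function(cache, dY) {
  list(dW = outer(as.numeric(cache$x), dY), db = dY,
       dX = as.numeric(cache$W %*% dY))
}

dropout_fwd <- function(x, p, train) {
  if (!train || p <= 0) return(list(out = x, mask = NULL))
  mask <- (runif(length(x)) >= p) / (1 - p)
  if (!is.null(dim(x))) dim(mask) <- dim(x)
  list(out = x * mask, mask = mask)
}
dropout_bwd <- function(cache, dY) if (is.null(cache$mask)) dY else dY * cache$mask

# Numerically stabilized softmax over the last dimension of an H x W x K
# logit stack (or a plain length-K vector).
softmax_last <- function(logits) {
  if (is.null(dim(logits))) {
    z <- logits - max(logits)
    e <- exp(z)
    return(e / sum(e))
  }
  d <- dim(logits)
  m <- matrix(logits, prod(d[1:2]), d[3])
  m <- m - apply(m, 1, max)
  e <- exp(m)
  p <- e / rowSums(e)
  dim(p) <- d
  p
}

# Cross-entropy over pixels; targets are 1-based class indices (H x W
# matrix). Optional per-class weights counter foreground/background
# imbalance: loss = sum_i w(t_i) * (-log p_i) / sum_i w(t_i).
pixel_ce <- function(logits, targets, class_weights = NULL) {
  d <- dim(logits)
  p <- softmax_last(logits)
  pm <- matrix(p, prod(d[1:2]), d[3])
  idx <- cbind(seq_len(prod(d[1:2])), as.integer(targets))
  if (is.null(class_weights)) {
    loss <- -mean(log(pmax(pm[idx], 1e-12)))
    g <- pm
    g[idx] <- g[idx] - 1
    g <- g / prod(d[1:2])
  } else {
    wpix <- class_weights[as.integer(targets)]
    wsum <- sum(wpix)
    loss <- sum(wpix * -log(pmax(pm[idx], 1e-12))) / wsum
    g <- pm
    g[idx] <- g[idx] - 1
    g <- g * (wpix / wsum)
  }
  dim(g) <- d
  list(loss = loss, grad = g)
}

# Soft-Dice loss on the foreground probability of a binary (K = 2) softmax,
# with its gradient in logit space. Optimizes the overlap metric directly,
# which counteracts foreground/background imbalance.
soft_dice_loss <- function(logits, targets, smooth = 1) {
  d <- dim(logits)
  p <- softmax_last(logits)
  p2 <- p[, , 2]
  t2 <- matrix(as.numeric(targets == 2L), d[1], d[2])
  inter <- sum(p2 * t2)
  denom <- sum(p2) + sum(t2) + smooth
  dice <- (2 * inter + smooth) / denom
  # dL/dp2 of L = 1 - (2I+s)/D with dI/dp2 = t2 and dD/dp2 = 1
  dLdp <- -(2 * t2 * denom - (2 * inter + smooth)) / denom^2
  dz2 <- dLdp * p2 * (1 - p2)
  g <- array(0, d)
  g[, , 2] <- dz2
  g[, , 1] <- -dz2
  list(loss = 1 - dice, grad = g)
}

vector_ce <- function(logits, target) {
  p <- softmax_last(logits)
  loss <- -log(max(p[target], 1e-12))
  g <- p
  g[target] <- g[target] - 1
  list(loss = loss, grad = g)
}

## --- parameter initialisation and Adam ------------------------------------

he_conv <- function(cin, cout, taps = 9L) {
  matrix(rnorm(taps * cin * cout, 0, sqrt(2 / (taps * cin))), taps * cin, cout)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

# One Adam step with L2 weight decay applied to weight matrices (not biases;
# bias entries are vectors). lr already includes any schedule.
adam_step <- function(params, grads, st, lr, wd = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t; bc2 <- 1 - beta2^st$t
  for (k in names(params)) {
    g <- grads[[k]]
    if (is.null(g)) next
    if (wd > 0 && !is.null(dim(params[[k]]))) g <- g + wd * params[[k]]
    st$m[[k]] <- beta1 * st$m[[k]] + (1 - beta1) * g
    st$v[[k]] <- beta2 * st$v[[k]] + (1 - beta2) * g * g
    mhat <- st$m[[k]] / bc1
    vhat <- st$v[[k]] / bc2
    params[[k]] <- params[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, st = st)
}

cosine_lr <- function(lr0, step, total_steps) {
  lr0 * 0.5 * (1 + cos(pi * pmin(step / max(total_steps, 1), 1)))
}

zero_like <- function(params) lapply(params, function(p) p * 0)

acc_grads <- function(acc, g) {
  for (k in names(g)) acc[[k]] <- acc[[k]] + g[[k]]
  acc
}
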