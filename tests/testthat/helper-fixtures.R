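# Shared fixtures, all generated in code.

random_image <- function(h = 8, w = 8, seed = 1, lo = 0, hi = 255) {
  set.seed(seed)
  array(runif(h * w * 3, lo, hi), c(h, w, 3))
}

constant_image <- function(h, w, value) {
  array(value, c(h, w, 3))
}

# A bright disk of given radius on a dark background (all channels equal).
disk_image <- function(n = 41, radius = 12, fg = 200, bg = 20) {
  ctr <- (n + 1) / 2
  X <- matrix(rep(seq_len(n), each = n), n, n)
  Y <- matrix(rep(seq_len(n), times = n), n, n)
  m <- matrix(bg, n, n)
  m[(X - ctr)^2 + (Y - ctr)^2 <= radius^2] <- fg
  array(rep(m, 3), c(n, n, 3))
}

# Horizontal bright tube (Gaussian cross-profile) through the image center.
tube_image <- function(n = 41, sigma = 2, fg = 180, bg = 20) {
  ctr <- (n + 1) / 2
  Y <- matrix(rep(seq_len(n), times = n), n, n)
  m <- bg + (fg - bg) * exp(-(Y - ctr)^2 / (2 * sigma^2))
  array(rep(m, 3), c(n, n, 3))
}

# Brute-force direct bilateral filtering of one channel (double loop over
# pixels and neighborhoods, reflected borders) -- the independent oracle.
bilateral_bruteforce <- function(m, sigma_s, sigma_r, radius) {
  h <- nrow(m); w <- ncol(m)
  refl <- function(i, n) {
    while (i < 1 || i > n) {
      if (i < 1) i <- 1 - i
      if (i > n) i <- 2 * n + 1 - i
    }
    i
  }
  out <- matrix(0, h, w)
  for (y in 1:h) for (x in 1:w) {
    num <- 0; den <- 0
    for (dy in -radius:radius) for (dx in -radius:radius) {
      yy <- refl(y + dy, h); xx <- refl(x + dx, w)
      wgt <- exp(-(dx^2 + dy^2) / (2 * sigma_s^2)) *
        exp(-(m[y, x] - m[yy, xx])^2 / (2 * sigma_r^2))
      num <- num + wgt * m[yy, xx]
      den <- den + wgt
    }
    out[y, x] <- num / den
  }
  out
}

# Brute-force dilated 3x3 convolution (zero padding), independent of the
# compiled im2col path. Weights in the package layout: row = tap + 9*(cin-1),
# taps enumerate (dy, dx) in {-1,0,1}^2 with dy fastest.
dilated_conv_bruteforce <- function(x, W, b, rate) {
  h <- dim(x)[1]; w <- dim(x)[2]; cin <- dim(x)[3]
  cout <- ncol(W)
  out <- array(0, c(h, w, cout))
  for (co in 1:cout) {
    acc <- matrix(b[co], h, w)
    for (ci in 1:cin) {
      for (dx in -1:1) for (dy in -1:1) {
        t <- (dy + 1) + 3 * (dx + 1)
        wv <- W[t + 1 + 9 * (ci - 1), co]
        if (wv == 0) next
        for (y in 1:h) for (xx in 1:w) {
          sy <- y + dy * rate; sx <- xx + dx * rate
          if (sy >= 1 && sy <= h && sx >= 1 && sx <= w)
            acc[y, xx] <- acc[y, xx] + wv * x[sy, sx, ci]
        }
      }
    }
    out[, , co] <- acc
  }
  out
}
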