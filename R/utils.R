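# Internal helpers shared across modules.

# Run expr with a temporary RNG state seeded at `seed`, restoring the caller's
# state afterwards so library functions never perturb user-level randomness.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Derive a per-stage seed from a global seed: stable, independent of locale,
# always below 2^31 so it is a valid R integer.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.double(seed) * 7919 + h) %% 2147483647)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

clip255 <- function(x) {
  x[x < 0] <- 0
  x[x > 255] <- 255
  x
}

# Rec. 601 luma; used for SSIM / gradient-magnitude summaries.
luminance <- function(img) {
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

assert_image <- function(img, name = "img") {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop(name, " must be an H x W x 3 array")
  if (any(!is.finite(img))) stop(name, " contains non-finite values")
  invisible(img)
}

# Reflect an out-of-range index vector back into 1..n ("symmetric" padding,
# whole-sample reflection: ... 3 2 1 | 1 2 3 ... n | n n-1 ...).
reflect_index <- function(idx, n) {
  if (n == 1L) return(rep(1L, length(idx)))
  period <- 2L * n
  m <- (idx - 1L) %% period
  m[m < 0] <- m[m < 0] + period
  out <- m + 1L
  hi <- out > n
  out[hi] <- period - out[hi] + 1L
  out
}

# Shift a matrix by (dy, dx) with reflected borders.
shift_reflect <- function(m, dy, dx) {
  h <- nrow(m); w <- ncol(m)
  m[reflect_index(seq_len(h) + dy, h), reflect_index(seq_len(w) + dx, w)]
}

# Shift a matrix by (dy, dx) filling with a constant.
shift_pad <- function(m, dy, dx, fill = 0) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  ys <- seq_len(h) + dy; xs <- seq_len(w) + dx
  oky <- ys >= 1 & ys <= h; okx <- xs >= 1 & xs <= w
  if (any(oky) && any(okx)) out[oky, okx] <- m[ys[oky], xs[okx]]
  out
}

per_channel <- function(img, f, ...) {
  out <- img
  for (c in 1:3) out[, , c] <- f(img[, , c], ...)
  out
}

# Bilinear reduction of an image or mask by an integer factor. Masks are
# re-binarized with a low threshold so thin structures survive.
downscale_image <- function(img, s) {
  if (s <= 1L) return(img)
  h <- nrow(img); w <- ncol(img)
  A <- interp_matrix(max(4L, h %/% s), h)
  B <- interp_matrix(max(4L, w %/% s), w)
  out <- array(0, c(nrow(A), nrow(B), dim(img)[3]))
  for (c in seq_len(dim(img)[3])) out[, , c] <- A %*% img[, , c] %*% t(B)
  out
}

downscale_mask <- function(mask, s) {
  if (s <= 1L) return(mask)
  h <- nrow(mask); w <- ncol(mask)
  A <- interp_matrix(max(4L, h %/% s), h)
  B <- interp_matrix(max(4L, w %/% s), w)
  m <- A %*% mask %*% t(B)
  matrix(as.integer(m > 0.25), nrow(A), nrow(B))
}
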