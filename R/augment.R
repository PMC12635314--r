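## Geometric augmentation: random rotation, width shift, zoom and horizontal
## flip applied jointly to image and mask, emulating capsule orientation and
## field-of-view variation. Fill outside the source is constant black, which
## matches the endoscope FOV border.

#' Augmentation configuration
#'
#' Defaults follow the standard WCE augmentation recipe: rotations up to
#' 20 degrees, width shifts up to 20%, zoom up to 20%, and horizontal
#' flipping, with four random variants per source image (so keeping the
#' original gives a five-fold dataset expansion).
#'
#' @param rotation_deg Maximum absolute rotation in degrees.
#' @param width_shift_frac Maximum horizontal shift as a fraction of width.
#' @param zoom_frac Maximum zoom deviation from 1 (scale drawn in
#'   `[1 - zoom_frac, 1 + zoom_frac]`).
#' @param horizontal_flip Allow a 50% random horizontal flip.
#' @param variants_per_image Number of random variants generated per image.
#' @param fill_mode `"constant-black"` (default) or `"reflect"`.
#' @return An `augment_config` list.
#' @export
augment_config <- function(rotation_deg = 20, width_shift_frac = 0.2,
                           zoom_frac = 0.2, horizontal_flip = TRUE,
                           variants_per_image = 4L,
                           fill_mode = c("constant-black", "reflect")) {
  fill_mode <- match.arg(fill_mode)
  if (width_shift_frac < 0 || width_shift_frac > 1 ||
      zoom_frac < 0 || zoom_frac > 1)
    stop("shift and zoom fractions must lie in [0, 1]")
  if (variants_per_image < 0) stop("variants_per_image must be >= 0")
  structure(list(rotation_deg = rotation_deg,
                 width_shift_frac = width_shift_frac,
                 zoom_frac = zoom_frac,
                 horizontal_flip = isTRUE(horizontal_flip),
                 variants_per_image = as.integer(variants_per_image),
                 fill_mode = fill_mode),
            class = "augment_config")
}

# Sample a 2D point map dst -> src for one channel. A is the 2x2 inverse
# linear part, b the offset, in (x, y) = (column, row) convention.
affine_sample_matrix <- function(m, A, b, interp = c("bilinear", "nearest"),
                                 fill = 0) {
  interp <- match.arg(interp)
  h <- nrow(m); w <- ncol(m)
  X <- rep(seq_len(w), each = h); Y <- rep(seq_len(h), times = w)
  sx <- A[1, 1] * X + A[1, 2] * Y + b[1]
  sy <- A[2, 1] * X + A[2, 2] * Y + b[2]
  if (interp == "nearest") {
    ix <- round(sx); iy <- round(sy)
    ok <- ix >= 1 & ix <= w & iy >= 1 & iy <= h
    out <- rep(fill, h * w)
    out[ok] <- m[cbind(iy[ok], ix[ok])]
    return(matrix(out, h, w))
  }
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0; fy <- sy - y0
  gather <- function(yy, xx) {
    ok <- xx >= 1 & xx <= w & yy >= 1 & yy <= h
    v <- rep(fill, h * w)
    v[ok] <- m[cbind(yy[ok], xx[ok])]
    v
  }
  v00 <- gather(y0, x0); v01 <- gather(y0, x0 + 1)
  v10 <- gather(y0 + 1, x0); v11 <- gather(y0 + 1, x0 + 1)
  out <- (1 - fy) * ((1 - fx) * v00 + fx * v01) +
         fy * ((1 - fx) * v10 + fx * v11)
  matrix(out, h, w)
}

# Build the dst -> src affine map for (flip, zoom, rotation, shift) about the
# image center. Forward transform: flip, then scale+rotate about center, then
# translate by tx.
make_affine <- function(h, w, theta_deg, tx, zoom, flip) {
  cx <- (w + 1) / 2; cy <- (h + 1) / 2
  th <- theta_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2) # columns: x,y images
  Fm <- diag(c(if (flip) -1 else 1, 1))
  M <- R %*% (zoom * Fm)                 # forward linear part
  A <- solve(M)                          # inverse for dst -> src
  ctr <- c(cx, cy)
  b <- ctr - A %*% (ctr + c(tx, 0))
  list(A = A, b = as.numeric(b))
}

apply_affine_item <- function(item, A, b) {
  img <- item$image
  for (c in 1:3) img[, , c] <- affine_sample_matrix(item$image[, , c], A, b,
                                                    "bilinear", fill = 0)
  mask <- affine_sample_matrix(item$mask, A, b, "nearest", fill = 0)
  out <- item
  out$image <- clip255(img)
  out$mask <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  out
}

# Horizontal flip about the vertical center line; exact involution.
flip_horizontal_item <- function(item) {
  out <- item
  out$image <- item$image[, ncol(item$mask):1, , drop = FALSE]
  out$mask <- item$mask[, ncol(item$mask):1, drop = FALSE]
  out
}

#' Generate random augmented variants of a labeled image
#'
#' Each variant applies one random geometric transform (rotation, width
#' shift, zoom, optional horizontal flip) jointly to the image and its mask;
#' the class label is preserved and output shape equals input shape. With
#' the identity configuration (all ranges zero, flip off) the output equals
#' the input exactly.
#'
#' @param item A `wce_labeled_image` (from [generate_phantom()] or built by
#'   hand with fields `image`, `mask`, `label`).
#' @param cfg An [augment_config()].
#' @param seed Integer seed for the random transform draws.
#' @return List of `cfg$variants_per_image` new `wce_labeled_image` items.
#' @export
augment <- function(item, cfg = augment_config(), seed = 1L) {
  if (is.null(item$image) || length(item$image) == 0L) stop("empty image")
  assert_image(item$image)
  with_seed(seed, {
    lapply(seq_len(cfg$variants_per_image), function(i) {
      theta <- runif(1, -cfg$rotation_deg, cfg$rotation_deg)
      tx <- runif(1, -cfg$width_shift_frac, cfg$width_shift_frac) *
        ncol(item$mask)
      zoom <- runif(1, 1 - cfg$zoom_frac, 1 + cfg$zoom_frac)
      flip <- cfg$horizontal_flip && runif(1) < 0.5
      if (theta == 0 && tx == 0 && zoom == 1 && !flip) return(item)
      af <- make_affine(nrow(item$mask), ncol(item$mask), theta, tx, zoom, flip)
      apply_affine_item(item, af$A, af$b)
    })
  })
}
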