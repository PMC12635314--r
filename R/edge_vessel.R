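## Enhancement chain: Gaussian smoothing, gradient fields, Canny edges,
## Hough-space edge linking, Hessian-eigenvalue (Frangi) vesselness, and the
## multiplicative edge/vessel enhancement feeding the segmenter.

gaussian_kernel_1d <- function(sigma, radius = NULL) {
  if (sigma <= 0) stop("sigma must be positive")
  if (is.null(radius)) radius <- max(1L, ceiling(3.5 * sigma))
  x <- (-radius):radius
  g <- exp(-x^2 / (2 * sigma^2))
  g / sum(g)
}

# Separable convolution of one channel with 1D kernels along rows (ky) and
# columns (kx), reflected borders.
sep_conv_channel <- function(m, kx, ky) {
  rx <- (length(kx) - 1L) / 2L; ry <- (length(ky) - 1L) / 2L
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_along(ky)) out <- out + ky[i] * shift_reflect(m, i - 1L - ry, 0L)
  out2 <- matrix(0, nrow(m), ncol(m))
  for (i in seq_along(kx)) out2 <- out2 + kx[i] * shift_reflect(out, 0L, i - 1L - rx)
  out2
}

gaussian_smooth_channel <- function(m, sigma) {
  g <- gaussian_kernel_1d(sigma)
  sep_conv_channel(m, g, g)
}

#' Gaussian smoothing of a color image
#'
#' Separable Gaussian convolution per channel with reflected borders and a
#' unit-sum kernel truncated at `ceiling(3.5 * sigma)` taps per side, so the
#' mean intensity is preserved.
#'
#' @param img H x W x 3 image.
#' @param sigma Gaussian standard deviation in pixels.
#' @return Smoothed image.
#' @export
gaussian_smooth <- function(img, sigma) {
  assert_image(img)
  per_channel(img, gaussian_smooth_channel, sigma = sigma)
}

gradient_channel <- function(m) {
  h <- nrow(m); w <- ncol(m)
  gx <- matrix(0, h, w); gy <- matrix(0, h, w)
  gx[, 2:(w - 1)] <- (m[, 3:w] - m[, 1:(w - 2)]) / 2
  gx[, 1] <- m[, 2] - m[, 1]; gx[, w] <- m[, w] - m[, w - 1]
  gy[2:(h - 1), ] <- (m[3:h, ] - m[1:(h - 2), ]) / 2
  gy[1, ] <- m[2, ] - m[1, ]; gy[h, ] <- m[h, ] - m[h - 1, ]
  list(gx = gx, gy = gy)
}

#' Intensity gradient field
#'
#' Central differences in the interior, one-sided differences at borders,
#' computed per channel. Magnitude is `sqrt(gx^2 + gy^2)`; orientation is
#' `atan2(gy, gx)` in (-pi, pi].
#'
#' @param img H x W x 3 image (at least 3 x 3).
#' @return List with `magnitude` and `orientation` (both H x W x 3).
#' @export
gradient_magnitude <- function(img) {
  assert_image(img)
  if (nrow(img) < 3 || ncol(img) < 3) stop("image must be at least 3 x 3")
  mag <- img * 0; ori <- img * 0
  for (c in 1:3) {
    g <- gradient_channel(img[, , c])
    mag[, , c] <- sqrt(g$gx^2 + g$gy^2)
    ori[, , c] <- atan2(g$gy, g$gx)
  }
  list(magnitude = mag, orientation = ori)
}

# Non-maximum suppression along the quantized gradient orientation.
nms_channel <- function(mag, gx, gy) {
  ang <- atan2(gy, gx)
  ang[ang < 0] <- ang[ang < 0] + pi
  sector <- as.integer(floor((ang + pi / 8) / (pi / 4))) %% 4L
  # sector 0: horizontal gradient -> compare left/right columns
  # sector 1: 45 deg; sector 2: vertical; sector 3: 135 deg
  n1 <- mag * 0; n2 <- mag * 0
  offs <- list(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))
  for (s in 0:3) {
    sel <- sector == s
    o <- offs[[s + 1L]]
    a <- shift_pad(mag, o[1], o[2]); b <- shift_pad(mag, -o[1], -o[2])
    n1[sel] <- a[sel]; n2[sel] <- b[sel]
  }
  keep <- mag >= n1 & mag >= n2 & mag > 0
  mag * keep
}

# 8-connected component labeling. EBImage::bwlabel is 4-connected; edge
# chains produced by non-maximum suppression step diagonally, so hysteresis
# needs diagonal adjacency. Labels the 4-connected components, then merges
# labels that touch diagonally with a small union-find.
label8 <- function(m) {
  lab <- EBImage::bwlabel(m)
  lab <- matrix(as.integer(lab), nrow(m), ncol(m))
  nl <- max(lab)
  if (nl <= 1L) return(lab)
  parent <- seq_len(nl)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  h <- nrow(lab); w <- ncol(lab)
  for (sh in list(c(1L, 1L), c(1L, -1L))) {
    a <- lab[1:(h - 1), if (sh[2] > 0) 1:(w - 1) else 2:w]
    b <- lab[2:h, if (sh[2] > 0) 2:w else 1:(w - 1)]
    sel <- a > 0L & b > 0L & a != b
    if (!any(sel)) next
    for (p in unique(a[sel] * (nl + 1L) + b[sel])) {
      i <- find(p %/% (nl + 1L)); j <- find(p %% (nl + 1L))
      if (i != j) parent[max(i, j)] <- min(i, j)
    }
  }
  roots <- vapply(seq_len(nl), find, integer(1))
  out <- lab
  out[lab > 0L] <- match(roots, sort(unique(roots)))[lab[lab > 0L]]
  out
}

# Remove one pixel (the weakest) from every fully set 2x2 block so edges
# stay one pixel wide.
thin_edges <- function(edges, strength) {
  for (iter in 1:8) {
    h <- nrow(edges); w <- ncol(edges)
    b <- edges[1:(h - 1), 1:(w - 1)] & edges[2:h, 1:(w - 1)] &
         edges[1:(h - 1), 2:w] & edges[2:h, 2:w]
    if (!any(b)) break
    idx <- which(b, arr.ind = TRUE)
    for (r in seq_len(nrow(idx))) {
      ys <- idx[r, 1] + 0:1; xs <- idx[r, 2] + 0:1
      blk <- strength[ys, xs]
      mn <- which(blk == min(blk))[1]
      edges[ys[(mn - 1) %% 2 + 1], xs[(mn - 1) %/% 2 + 1]] <- FALSE
    }
  }
  edges
}

#' Canny edge detection
#'
#' Per channel: Gaussian smoothing, gradient, non-maximum suppression along
#' the quantized gradient orientation, and double-threshold hysteresis
#' (weak edges survive only when 8-connected to a strong edge). The three
#' channel maps are reduced by any-channel OR and thinned so no 2 x 2 block
#' is fully set.
#'
#' @param img H x W x 3 image.
#' @param sigma Smoothing sigma in pixels (default 1.4).
#' @param low_frac,high_frac Hysteresis thresholds as fractions of the
#'   maximum suppressed gradient magnitude; must satisfy
#'   `0 < low_frac < high_frac < 1`.
#' @return A `wce_edge_map`: logical H x W matrix with attribute
#'   `"thresholds"` (per-channel low/high values used).
#' @export
canny_edges <- function(img, sigma = 1.4, low_frac = 0.1, high_frac = 0.2) {
  assert_image(img)
  if (!(low_frac > 0 && low_frac < high_frac && high_frac < 1))
    stop("need 0 < low_frac < high_frac < 1")
  h <- nrow(img); w <- ncol(img)
  edges <- matrix(FALSE, h, w)
  strength <- matrix(0, h, w)
  thr <- matrix(0, 3, 2, dimnames = list(c("R", "G", "B"), c("low", "high")))
  for (c in 1:3) {
    sm <- gaussian_smooth_channel(img[, , c], sigma)
    g <- gradient_channel(sm)
    mag <- sqrt(g$gx^2 + g$gy^2)
    nms <- nms_channel(mag, g$gx, g$gy)
    mx <- max(nms)
    if (mx == 0) next
    high <- high_frac * mx; low <- low_frac * mx
    thr[c, ] <- c(low, high)
    weak <- nms >= low
    strong <- nms >= high
    if (!any(strong)) next
    lab <- label8(weak)
    keep_labels <- unique(lab[strong])
    ch_edges <- weak & (lab %in% keep_labels)
    edges <- edges | matrix(ch_edges, h, w)
    strength <- pmax(strength, nms)
  }
  edges <- thin_edges(edges, strength)
  structure(edges, class = c("wce_edge_map", "matrix"), thresholds = thr)
}

#' Hough-space edge linking
#'
#' Builds the standard (rho, theta) line accumulator over edge pixels
#' (rho = x cos(theta) + y sin(theta), theta in [0, pi), signed rho),
#' accepts peaks with at least `vote_frac` of the maximum vote, and bridges
#' gaps of at most `gap_px` pixels between consecutive edge pixels lying
#' within 1.5 px of an accepted line. Bridging only adds pixels: the output
#' edge map is a superset of the input.
#'
#' @param edges Logical H x W edge map (e.g. from [canny_edges()]).
#' @param rho_res Accumulator rho resolution in pixels (default 1).
#' @param theta_res Theta resolution in radians (default 1 degree).
#' @param vote_frac Peak acceptance threshold as a fraction of the maximum
#'   accumulator vote (default 0.3).
#' @param gap_px Maximum gap length bridged along a line (default 5).
#' @param max_lines Cap on the number of reported lines (default 32).
#' @return List with `edges` (linked edge map) and `lines` (list of
#'   rho/theta/votes/support records).
#' @export
hough_link <- function(edges, rho_res = 1, theta_res = pi / 180,
                       vote_frac = 0.3, gap_px = 5, max_lines = 32L) {
  if (rho_res <= 0 || theta_res <= 0) stop("resolutions must be positive")
  em <- matrix(as.logical(edges), nrow(edges), ncol(edges))
  pix <- which(em, arr.ind = TRUE)
  if (nrow(pix) == 0L)
    return(list(edges = em, lines = list()))
  ys <- pix[, 1]; xs <- pix[, 2]
  h <- nrow(em); w <- ncol(em)
  diag_len <- sqrt(h^2 + w^2)
  thetas <- seq(0, pi - theta_res / 2, by = theta_res)
  n_rho <- as.integer(round(2 * diag_len / rho_res)) + 1L
  acc <- matrix(0L, n_rho, length(thetas))
  cth <- cos(thetas); sth <- sin(thetas)
  for (j in seq_along(thetas)) {
    rho <- xs * cth[j] + ys * sth[j]
    bin <- as.integer(round((rho + diag_len) / rho_res)) + 1L
    tab <- tabulate(bin, nbins = n_rho)
    acc[, j] <- tab
  }
  vmax <- max(acc)
  peaks <- which(acc >= vote_frac * vmax & acc >= 2L, arr.ind = TRUE)
  if (nrow(peaks) > 0L) {
    ord <- order(acc[peaks], decreasing = TRUE)
    peaks <- peaks[ord, , drop = FALSE]
    if (nrow(peaks) > max_lines) peaks <- peaks[seq_len(max_lines), , drop = FALSE]
  }
  out <- em
  lines <- list()
  for (r in seq_len(nrow(peaks))) {
    j <- peaks[r, 2]
    rho <- (peaks[r, 1] - 1L) * rho_res - diag_len
    d <- abs(xs * cth[j] + ys * sth[j] - rho)
    sel <- d <= 1.5
    if (sum(sel) < 2L) next
    sx <- xs[sel]; sy <- ys[sel]
    tpos <- -sx * sth[j] + sy * cth[j]
    o <- order(tpos)
    sx <- sx[o]; sy <- sy[o]
    n <- length(sx)
    seg <- sqrt(diff(sx)^2 + diff(sy)^2)
    bridge <- which(seg > sqrt(2) + 1e-9 & seg <= gap_px)
    for (bidx in bridge) {
      npts <- max(2L, ceiling(seg[bidx]) + 1L)
      bx <- round(seq(sx[bidx], sx[bidx + 1], length.out = npts))
      by <- round(seq(sy[bidx], sy[bidx + 1], length.out = npts))
      out[cbind(by, bx)] <- TRUE
    }
    lines[[length(lines) + 1L]] <- list(
      rho = rho, theta = thetas[j], votes = acc[peaks[r, 1], j],
      support = cbind(y = sy, x = sx))
  }
  list(edges = out, lines = lines)
}

#' Frangi vesselness configuration
#'
#' @param beta Blobness sensitivity (default 0.5); smaller values respond
#'   more selectively to elongated, tube-like structures.
#' @param c_sensitivity Structure-strength sensitivity; `NULL` (default)
#'   auto-sets it per channel to half the maximum Hessian Frobenius norm.
#' @param sigma_scales Gaussian-derivative scales in pixels (default 2;
#'   multiple scales are reduced by the pixelwise maximum).
#' @param sign_gating When `TRUE`, zero the response where the principal
#'   eigenvalue is positive (keeps only bright tubular structures).
#' @param strict_paper_s When `TRUE`, use `S = sqrt(2) * |lambda1|` instead
#'   of the classical `S = sqrt(lambda1^2 + lambda2^2)`.
#' @return A `frangi_config` list.
#' @export
frangi_config <- function(beta = 0.5, c_sensitivity = NULL, sigma_scales = 2,
                          sign_gating = FALSE, strict_paper_s = FALSE) {
  if (beta <= 0) stop("beta must be positive")
  if (any(sigma_scales <= 0)) stop("scales must be positive")
  structure(list(beta = beta, c_sensitivity = c_sensitivity,
                 sigma_scales = sigma_scales,
                 sign_gating = isTRUE(sign_gating),
                 strict_paper_s = isTRUE(strict_paper_s)),
            class = "frangi_config")
}

#' Scalar vesselness response
#'
#' The tube-emphasis response for one eigenvalue pair:
#' `V = exp(-Rb^2 / (2 beta^2)) * (1 - exp(-S^2 / (2 c^2)))` with blobness
#' ratio `Rb = |lambda2| / |lambda1|` (defined as 0 where `lambda1 = 0`, in
#' which case V is 0) and structure strength
#' `S = sqrt(lambda1^2 + lambda2^2)` (or `sqrt(2) |lambda1|` in strict
#' mode). Vectorized over the eigenvalue arguments.
#'
#' @param lambda1,lambda2 Hessian eigenvalues ordered `|lambda1| >= |lambda2|`.
#' @param beta,c_sensitivity Sensitivity parameters.
#' @param strict_paper_s Use the `sqrt(2) |lambda1|` strength variant.
#' @return Vesselness values in [0, 1).
#' @export
frangi_response <- function(lambda1, lambda2, beta = 0.5, c_sensitivity = 1,
                            strict_paper_s = FALSE) {
  Rb <- ifelse(lambda1 == 0, 0, abs(lambda2) / abs(lambda1))
  S <- if (strict_paper_s) sqrt(2) * abs(lambda1)
       else sqrt(lambda1^2 + lambda2^2)
  V <- exp(-Rb^2 / (2 * beta^2)) * (1 - exp(-S^2 / (2 * c_sensitivity^2)))
  V[lambda1 == 0] <- 0
  V
}

# Gaussian-derivative Hessian of one channel at scale sigma, gamma-normalized
# by sigma^2 so responses are comparable across scales.
hessian_channel <- function(m, sigma) {
  r <- max(1L, ceiling(3.5 * sigma))
  x <- (-r):r
  g0 <- exp(-x^2 / (2 * sigma^2)); g0 <- g0 / sum(g0)
  g1 <- -x / sigma^2 * g0
  g2 <- (x^2 - sigma^2) / sigma^4 * g0
  # truncation leaves tiny nonzero moments; enforce the exact DC-invariance
  # of derivative kernels so constant images give an exactly zero Hessian
  g1 <- (g1 - rev(g1)) / 2
  g2 <- g2 - mean(g2)
  s2 <- sigma^2
  list(hxx = s2 * sep_conv_channel(m, g2, g0),
       hyy = s2 * sep_conv_channel(m, g0, g2),
       hxy = s2 * sep_conv_channel(m, g1, g1))
}

#' Frangi vesselness map
#'
#' Per channel and per scale, computes the Gaussian-derivative Hessian,
#' orders its eigenvalues by magnitude (`|lambda1| >= |lambda2|`), and
#' applies [frangi_response()]; multiple scales are reduced by the
#' pixelwise maximum. A constant image yields an identically zero map.
#'
#' @param img H x W x 3 image.
#' @param cfg A [frangi_config()].
#' @return H x W x 3 vesselness array with values in [0, 1).
#' @export
frangi_vesselness <- function(img, cfg = frangi_config()) {
  assert_image(img)
  V <- img * 0
  for (c in 1:3) {
    vc <- matrix(0, nrow(img), ncol(img))
    for (sigma in cfg$sigma_scales) {
      hs <- hessian_channel(img[, , c], sigma)
      half_diff <- (hs$hxx - hs$hyy) / 2
      root <- sqrt(half_diff^2 + hs$hxy^2)
      mean_h <- (hs$hxx + hs$hyy) / 2
      la <- mean_h + root; lb <- mean_h - root
      swap <- abs(lb) > abs(la)
      l1 <- ifelse(swap, lb, la); l2 <- ifelse(swap, la, lb)
      # numerically zero Hessians (constant/flat channels) give no response;
      # the tolerance is relative to the channel's intensity scale
      frob <- sqrt(l1^2 + l2^2)
      tol <- 1e-9 * (max(abs(img[, , c])) + 1)
      cs <- cfg$c_sensitivity
      if (is.null(cs)) {
        frob_max <- sqrt(max(frob^2))
        if (frob_max <= tol) next
        cs <- frob_max / 2
      }
      v <- frangi_response(l1, l2, cfg$beta, cs, cfg$strict_paper_s)
      v[frob <= tol] <- 0
      if (cfg$sign_gating) v[l1 > 0] <- 0
      vc <- pmax(vc, v)
    }
    V[, , c] <- vc
  }
  V
}

#' Blend an edge-enhanced image with its vesselness map
#'
#' Computes `alpha * (V * E) + (1 - alpha) * E`, clipped to [0, 255].
#' `alpha = 1` reproduces the pure multiplicative vesselness weighting;
#' the pipeline default `alpha = 0.5` keeps tissue context visible.
#'
#' @param edges_img Edge-enhanced image E (H x W x 3).
#' @param V Vesselness map (H x W x 3, in [0, 1)).
#' @param alpha Blend weight in [0, 1].
#' @return Enhanced image on the 0-255 scale.
#' @export
enhance <- function(edges_img, V, alpha = 0.5) {
  if (!all(dim(edges_img) == dim(V))) stop("shape mismatch between E and V")
  clip255(alpha * (V * edges_img) + (1 - alpha) * edges_img)
}

#' Enhancement-chain configuration
#'
#' @param canny_sigma,low_frac,high_frac Canny parameters.
#' @param rho_res,theta_res,vote_frac,gap_px Hough linking parameters.
#' @param frangi A [frangi_config()].
#' @param alpha Vesselness blend weight (default 0.5).
#' @param edge_gain Multiplicative boost applied to linked-edge pixels when
#'   forming the edge-enhanced image E (default 1.5).
#' @return An `enhance_config` list.
#' @export
enhance_config <- function(canny_sigma = 1.4, low_frac = 0.1, high_frac = 0.2,
                           rho_res = 1, theta_res = pi / 180, vote_frac = 0.3,
                           gap_px = 5, frangi = frangi_config(),
                           alpha = 0.5, edge_gain = 1.5) {
  structure(list(canny_sigma = canny_sigma, low_frac = low_frac,
                 high_frac = high_frac, rho_res = rho_res,
                 theta_res = theta_res, vote_frac = vote_frac,
                 gap_px = gap_px, frangi = frangi, alpha = alpha,
                 edge_gain = edge_gain), class = "enhance_config")
}

#' Run the full enhancement chain on a preprocessed image
#'
#' Canny edges, Hough linking, edge-boosted image E (linked-edge pixels
#' scaled by `edge_gain`), Frangi vesselness on E, and the final blend
#' [enhance()]. Returns the enhanced image plus intermediates for
#' inspection and for the segmenter's vesselness input channel.
#'
#' @param img Preprocessed H x W x 3 image.
#' @param cfg An [enhance_config()].
#' @return List with `enhanced`, `edges` (linked map), `lines`,
#'   `vesselness`, and `edge_image` (E).
#' @export
enhance_image <- function(img, cfg = enhance_config()) {
  assert_image(img)
  ed <- canny_edges(img, cfg$canny_sigma, cfg$low_frac, cfg$high_frac)
  hl <- hough_link(ed, cfg$rho_res, cfg$theta_res, cfg$vote_frac, cfg$gap_px)
  E <- img
  boost <- which(hl$edges)
  for (c in 1:3) {
    ch <- E[, , c]
    ch[boost] <- ch[boost] * cfg$edge_gain
    E[, , c] <- ch
  }
  E <- clip255(E)
  V <- frangi_vesselness(E, cfg$frangi)
  list(enhanced = enhance(E, V, cfg$alpha), edges = hl$edges,
       lines = hl$lines, vesselness = V, edge_image = E)
}
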