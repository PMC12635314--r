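## Illumination-correcting preprocessing: per-channel clipped histogram
## equalization (cap each histogram bin at a threshold, redistribute the
## clipped mass uniformly over all 256 bins, then remap through the CDF)
## followed by a bilateral-filtered Retinex decomposition that divides out
## the smooth illumination field and keeps the reflectance.

#' Clipped-histogram-equalization configuration
#'
#' @param clip_mode `"fraction_of_peak"` derives the per-channel clip
#'   threshold as `clip_fraction` times the tallest histogram bin of that
#'   channel; `"absolute"` uses `clip_absolute` counts directly.
#' @param clip_fraction Fraction of the histogram peak, default 0.02 (2% of
#'   the peak bin count per channel).
#' @param clip_absolute Absolute bin cap (counts), used in `"absolute"` mode.
#' @return A `clip_he_config` list.
#' @export
clip_he_config <- function(clip_mode = c("fraction_of_peak", "absolute"),
                           clip_fraction = 0.02, clip_absolute = NULL) {
  clip_mode <- match.arg(clip_mode)
  if (clip_mode == "fraction_of_peak" &&
      (clip_fraction <= 0 || clip_fraction > 1))
    stop("clip_fraction must lie in (0, 1]")
  if (clip_mode == "absolute" &&
      (is.null(clip_absolute) || clip_absolute <= 0))
    stop("clip_absolute must be a positive count")
  structure(list(clip_mode = clip_mode, clip_fraction = clip_fraction,
                 clip_absolute = clip_absolute), class = "clip_he_config")
}

#' Per-channel intensity histogram
#'
#' Counts pixels by rounded intensity over the 256 levels 0..255.
#'
#' @param img H x W x 3 image on the 0-255 scale.
#' @param channel 1 (R), 2 (G) or 3 (B); channel names `"R"/"G"/"B"` also work.
#' @return A `channel_histogram`: list with `counts` (length 256), `channel`,
#'   and `total` (= M x N).
#' @export
channel_histogram <- function(img, channel) {
  assert_image(img)
  if (is.character(channel)) channel <- match(channel, c("R", "G", "B"))
  v <- round(img[, , channel])
  if (any(v < 0 | v > 255)) stop("intensities outside [0, 255]")
  counts <- tabulate(as.integer(v) + 1L, nbins = 256L)
  structure(list(counts = as.numeric(counts), channel = channel,
                 total = length(v)), class = "channel_histogram")
}

#' Clip histogram bins and redistribute the excess
#'
#' Each bin is capped at the clip threshold T; the total excess E is added
#' back as E/256 to every bin (fractional counts allowed), so the pixel
#' count is conserved exactly.
#'
#' @param h A [channel_histogram()].
#' @param cfg A [clip_he_config()].
#' @return A `channel_histogram` with redistributed (possibly fractional)
#'   counts; the threshold used is attached as attribute `"T_clip"`.
#' @export
clip_redistribute <- function(h, cfg = clip_he_config()) {
  if (!inherits(h, "channel_histogram")) stop("h must be a channel_histogram")
  T_clip <- if (cfg$clip_mode == "fraction_of_peak")
    cfg$clip_fraction * max(h$counts) else cfg$clip_absolute
  if (!is.finite(T_clip) || T_clip <= 0)
    stop("clip threshold must be positive (empty histogram?)")
  clipped <- pmin(h$counts, T_clip)
  excess <- sum(pmax(0, h$counts - T_clip))
  out <- h
  out$counts <- clipped + excess / 256
  attr(out, "T_clip") <- T_clip
  out
}

#' Clipped histogram equalization of all three channels
#'
#' Per channel: histogram, clip + redistribute, cumulative distribution
#' C(i) = cumsum(H_final)/MN, and remap I' = 255 * C(I). The remap is
#' monotone non-decreasing in input intensity and the output stays within
#' [0, 255].
#'
#' @param img H x W x 3 image on the 0-255 scale.
#' @param cfg A [clip_he_config()].
#' @return Equalized image (float, 0-255).
#' @export
equalize_channels <- function(img, cfg = clip_he_config()) {
  assert_image(img)
  if (length(img[, , 1]) == 0L) stop("degenerate zero-pixel image")
  out <- img
  for (c in 1:3) {
    h <- channel_histogram(img, c)
    hf <- clip_redistribute(h, cfg)
    cdf <- cumsum(hf$counts) / hf$total
    v <- as.integer(round(img[, , c])) + 1L
    out[, , c] <- matrix(255 * cdf[v], nrow(img), ncol(img))
  }
  out
}

#' Bilateral filter configuration
#'
#' @param sigma_s Spatial Gaussian width in pixels (default 3).
#' @param sigma_r Range (intensity) Gaussian width in intensity units
#'   (default 25 on the 0-255 scale).
#' @param radius Neighborhood half-size in pixels; default `3 * sigma_s`.
#' @return A `bilateral_config` list.
#' @export
bilateral_config <- function(sigma_s = 3, sigma_r = 25, radius = NULL) {
  if (sigma_s <= 0 || sigma_r <= 0) stop("sigma_s and sigma_r must be positive")
  if (is.null(radius)) radius <- ceiling(3 * sigma_s)
  if (radius < 1) stop("radius must be >= 1")
  structure(list(sigma_s = sigma_s, sigma_r = sigma_r,
                 radius = as.integer(radius)), class = "bilateral_config")
}

bilateral_channel <- function(m, sigma_s, sigma_r, radius) {
  num <- matrix(0, nrow(m), ncol(m))
  den <- matrix(0, nrow(m), ncol(m))
  inv2ss <- 1 / (2 * sigma_s^2); inv2sr <- 1 / (2 * sigma_r^2)
  for (dx in -radius:radius) {
    for (dy in -radius:radius) {
      ws <- exp(-(dx * dx + dy * dy) * inv2ss)
      sh <- shift_reflect(m, dy, dx)
      wr <- exp(-(m - sh)^2 * inv2sr)
      wgt <- ws * wr
      num <- num + wgt * sh
      den <- den + wgt
    }
  }
  num / den
}

#' Edge-preserving bilateral filter
#'
#' Per channel, each output pixel is the weighted mean of its neighborhood,
#' with weights the product of a spatial Gaussian on pixel distance and a
#' range Gaussian on intensity difference; borders are handled by reflecting
#' the image. With a very large `sigma_r` the filter degenerates to a plain
#' (truncated) Gaussian blur.
#'
#' @param img H x W x 3 image.
#' @param cfg A [bilateral_config()].
#' @return Filtered image, bounded by each channel's min and max.
#' @export
bilateral_filter <- function(img, cfg = bilateral_config()) {
  assert_image(img)
  if (cfg$radius > min(dim(img)[1:2]))
    stop("bilateral radius exceeds image size")
  per_channel(img, bilateral_channel, sigma_s = cfg$sigma_s,
              sigma_r = cfg$sigma_r, radius = cfg$radius)
}

#' Retinex decomposition via bilateral illumination estimation
#'
#' Estimates the illumination L as the bilateral filtering of the input and
#' recovers reflectance R = I / (L + epsilon). The reconstruction identity
#' R * (L + epsilon) = I holds to float precision.
#'
#' @param img H x W x 3 image (typically the equalized image).
#' @param bcfg A [bilateral_config()].
#' @param epsilon Small positive constant guarding the division (intensity
#'   units; default 0.01).
#' @return A `retinex_decomposition` list with `illumination`, `reflectance`,
#'   and `epsilon`.
#' @export
retinex_reflectance <- function(img, bcfg = bilateral_config(), epsilon = 0.01) {
  if (epsilon <= 0) stop("epsilon must be positive")
  assert_image(img)
  L <- bilateral_filter(img, bcfg)
  R <- img / (L + epsilon)
  structure(list(illumination = L, reflectance = R, epsilon = epsilon),
            class = "retinex_decomposition")
}

#' Full preprocessing configuration
#'
#' The default bilateral setting for the Retinex illumination estimate is
#' wider than the generic [bilateral_config()] default (`sigma_s = 8`,
#' `sigma_r = 80`, radius `2 sigma_s`): illumination is a smooth field, so
#' its estimate must average over scales larger than the lesions, otherwise
#' an edge-preserving filter absorbs the lesions into the illumination and
#' the reflectance loses the diagnostic color contrast.
#'
#' @param clip A [clip_he_config()].
#' @param bilateral A [bilateral_config()] for the illumination estimate.
#' @param epsilon Retinex division guard.
#' @param rescale_quantiles Reflectance quantiles mapped to 0 and 255 in the
#'   per-image affine rescale (default `c(0.01, 0.99)`, values beyond them
#'   clipped); robust against extreme reflectance ratios at specular
#'   highlights.
#' @param illum_scale Downsampling factor for the illumination estimate
#'   (default 1, the full-resolution bilateral estimate): with a factor
#'   `s > 1` the image is bilinearly reduced, bilateral filtered with
#'   correspondingly scaled spatial parameters, and the estimate upsampled
#'   back, cutting the bilateral cost roughly by `s^4` at the price of a
#'   slightly noisier reflectance. Useful for quick passes over large
#'   frames.
#' @param refine_model Optional trained refinement network from
#'   [refine_train()]; `NULL` skips refinement (the deterministic path).
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(clip = clip_he_config(),
                              bilateral = bilateral_config(sigma_s = 8,
                                                           sigma_r = 80,
                                                           radius = 16),
                              epsilon = 0.01,
                              rescale_quantiles = c(0.01, 0.99),
                              illum_scale = 1L,
                              refine_model = NULL) {
  if (illum_scale < 1) stop("illum_scale must be >= 1")
  structure(list(clip = clip, bilateral = bilateral, epsilon = epsilon,
                 rescale_quantiles = rescale_quantiles,
                 illum_scale = as.integer(illum_scale),
                 refine_model = refine_model), class = "preprocess_config")
}

# Illumination estimate for the preprocessing path: bilateral filtering,
# optionally at reduced resolution with scaled spatial parameters.
illum_estimate <- function(img, cfg) {
  s <- cfg$illum_scale
  if (s <= 1L) return(bilateral_filter(img, cfg$bilateral))
  h <- nrow(img); w <- ncol(img)
  hs <- max(8L, ceiling(h / s)); ws <- max(8L, ceiling(w / s))
  if (hs >= h || ws >= w) return(bilateral_filter(img, cfg$bilateral))
  Ad <- interp_matrix(hs, h); Bd <- interp_matrix(ws, w)
  Au <- interp_matrix(h, hs); Bu <- interp_matrix(w, ws)
  bc <- cfg$bilateral
  bsmall <- bilateral_config(max(0.5, bc$sigma_s / s), bc$sigma_r,
                             max(2L, ceiling(bc$radius / s)))
  small <- array(0, c(hs, ws, 3L))
  for (c in 1:3) small[, , c] <- Ad %*% img[, , c] %*% t(Bd)
  smallL <- bilateral_filter(small, bsmall)
  L <- img
  for (c in 1:3) L[, , c] <- Au %*% smallL[, , c] %*% t(Bu)
  L
}

#' Preprocess one image: equalize, Retinex, rescale, optional refinement
#'
#' Runs clipped histogram equalization, recovers the bilateral-Retinex
#' reflectance, affinely rescales the reflectance to [0, 255] per image
#' (mapping the `rescale_quantiles` to the range ends and clipping beyond;
#' reflectance is a dimensionless ratio whose scale is otherwise
#' arbitrary), and optionally applies the residual refinement network.
#' Deterministic for a fixed input and configuration.
#'
#' @param img H x W x 3 image on the 0-255 scale.
#' @param cfg A [preprocess_config()].
#' @return Preprocessed image on the 0-255 scale.
#' @export
preprocess_image <- function(img, cfg = preprocess_config()) {
  eq <- equalize_channels(img, cfg$clip)
  L <- illum_estimate(eq, cfg)
  R <- eq / (L + cfg$epsilon)
  q <- stats::quantile(R, cfg$rescale_quantiles, names = FALSE)
  out <- if (q[2] > q[1]) (R - q[1]) / (q[2] - q[1]) * 255 else R * 0
  out <- clip255(out)
  if (!is.null(cfg$refine_model)) out <- refine_apply(out, cfg$refine_model)
  out
}
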