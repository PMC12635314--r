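## Synthetic capsule-endoscopy phantoms.
##
## Phantoms emulate the statistical structure of WCE frames: a circular
## field of view, smooth illumination falloff, mucosal texture, specular
## highlights, sensor noise, and one of six lesion archetypes drawn with
## class-specific color and geometry. They make every downstream stage
## testable without any external dataset.

#' Specification of one synthetic WCE phantom
#'
#' @param class_label One of [wce_classes()].
#' @param height,width Image size in pixels.
#' @param lesion_count Number of discrete lesions (blobs, patches or streaks
#'   depending on class). Forced to the class default when `NULL`.
#' @param lesion_radius_range Length-2 numeric, lesion radius range in pixels;
#'   defaults scale with image size.
#' @param vessel_count Number of bright tubular vessels (Vascular lesion
#'   class); other classes carry only faint background vasculature.
#' @param vessel_sigma Gaussian half-width of vessel tubes in pixels.
#' @param illumination_strength Depth of the smooth illumination falloff,
#'   in [0, 1]; 0 gives flat lighting.
#' @param specular_count Number of small saturated specular highlights.
#' @param noise_sd Standard deviation of additive sensor noise (intensity
#'   units on the 0-255 scale).
#' @param seed Integer seed; the phantom is a pure function of the spec.
#' @return A `wce_phantom_spec` list.
#' @export
phantom_spec <- function(class_label,
                         height = 64, width = 64,
                         lesion_count = NULL,
                         lesion_radius_range = NULL,
                         vessel_count = NULL,
                         vessel_sigma = NULL,
                         illumination_strength = 0.35,
                         specular_count = 3,
                         noise_sd = 3,
                         seed = 1L) {
  if (!is.character(class_label) || length(class_label) != 1L ||
      !(class_label %in% WCE_CLASSES))
    stop("unknown class label: ", paste(class_label, collapse = ", "))
  if (height <= 0 || width <= 0) stop("image dimensions must be positive")
  s <- min(height, width)
  defaults <- switch(class_label,
    "Active bleeding"    = list(lesions = 2L, vessels = 0L),
    "Coagulated blood"   = list(lesions = 2L, vessels = 0L),
    "Esophagitis"        = list(lesions = 3L, vessels = 0L),
    "Normal"             = list(lesions = 0L, vessels = 0L),
    "Ulcerative colitis" = list(lesions = 2L, vessels = 0L),
    "Vascular lesion"    = list(lesions = 0L, vessels = 3L))
  if (is.null(lesion_count)) lesion_count <- defaults$lesions
  if (is.null(vessel_count)) vessel_count <- defaults$vessels
  if (is.null(lesion_radius_range))
    lesion_radius_range <- c(0.09, 0.16) * s
  if (is.null(vessel_sigma)) vessel_sigma <- max(1.2, 0.028 * s)
  if (class_label == "Normal") { lesion_count <- 0L; vessel_count <- 0L }
  if (lesion_count < 0 || vessel_count < 0 || specular_count < 0)
    stop("counts must be non-negative")
  if (any(lesion_radius_range <= 0)) stop("lesion_radius_range must be positive")
  if (illumination_strength < 0 || illumination_strength > 1)
    stop("illumination_strength must lie in [0, 1]")
  structure(list(
    height = as.integer(height), width = as.integer(width),
    class_label = class_label,
    lesion_count = as.integer(lesion_count),
    lesion_radius_range = as.numeric(lesion_radius_range),
    vessel_count = as.integer(vessel_count),
    vessel_sigma = as.numeric(vessel_sigma),
    illumination_strength = as.numeric(illumination_strength),
    specular_count = as.integer(specular_count),
    noise_sd = as.numeric(noise_sd),
    seed = as.integer(seed)
  ), class = "wce_phantom_spec")
}

# Class-archetype colors on the 0-255 scale (R, G, B).
phantom_palette <- function() list(
  mucosa     = c(185, 125, 110),
  active     = c(208, 32, 28),
  coagulated = c(86, 22, 28),
  vessel     = c(212, 48, 44),
  streak     = c(235, 95, 85),
  uc_center  = c(228, 212, 182),
  uc_rim     = c(196, 58, 52)
)

# Soft irregular blob support in [0, 1]: a wobbled-radius disk with a ~1.5 px
# smooth edge. X, Y are pixel coordinate matrices (x = column, y = row).
blob_support <- function(X, Y, cx, cy, r0, wobble = 0.30, nharm = 4L) {
  dx <- X - cx; dy <- Y - cy
  rad <- sqrt(dx^2 + dy^2)
  phi <- atan2(dy, dx)
  amp <- runif(nharm, 0, wobble / nharm * 2)
  pha <- runif(nharm, 0, 2 * pi)
  boundary <- r0 * (1 + Reduce(`+`, lapply(seq_len(nharm), function(k)
    amp[k] * cos(k * phi + pha[k]))))
  clip01((boundary - rad) / 1.5 + 0.5)
}

# Gaussian-profile support of a random smooth tube (quadratic Bezier curve).
tube_support <- function(X, Y, p0, p1, p2, sigma, npts = 160L) {
  t <- seq(0, 1, length.out = npts)
  bx <- (1 - t)^2 * p0[1] + 2 * (1 - t) * t * p1[1] + t^2 * p2[1]
  by <- (1 - t)^2 * p0[2] + 2 * (1 - t) * t * p1[2] + t^2 * p2[2]
  d2 <- matrix(Inf, nrow(X), ncol(X))
  for (i in seq_len(npts)) {
    dd <- (X - bx[i])^2 + (Y - by[i])^2
    d2 <- pmin(d2, dd)
  }
  exp(-d2 / (2 * sigma^2))
}

# Low-frequency random field in [-1, 1]-ish range: blurred white noise,
# normalized to unit sd.
smooth_field <- function(h, w, sigma) {
  f <- gaussian_smooth_channel(matrix(rnorm(h * w), h, w), sigma)
  f / max(sd(f), 1e-12)
}

blend_color <- function(img, weight, color) {
  for (c in 1:3) img[, , c] <- img[, , c] * (1 - weight) + color[c] * weight
  img
}

#' Generate one labeled synthetic phantom
#'
#' Deterministic for a fixed spec (the seed is part of the spec). Lesion
#' appearance follows the class archetype: Active bleeding gives bright-red
#' irregular blobs (R much greater than G, B); Coagulated blood dark-maroon
#' compact blobs; Vascular lesion thin bright-red tubes; Esophagitis reddish
#' streaks; Ulcerative colitis pale patches with red rims; Normal is texture
#' only. The mask marks lesion pixels and is empty for Normal.
#'
#' @param spec A [phantom_spec()].
#' @return A `wce_labeled_image` list with fields `image` (H x W x 3, 0-255),
#'   `mask` (H x W 0/1), `label`, and `spec`.
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "wce_phantom_spec")) stop("spec must be a phantom_spec()")
  with_seed(spec$seed, generate_phantom_impl(spec))
}

generate_phantom_impl <- function(spec) {
  h <- spec$height; w <- spec$width
  pal <- phantom_palette()
  X <- matrix(rep(seq_len(w), each = h), h, w)   # x = column
  Y <- matrix(rep(seq_len(h), times = w), h, w)  # y = row
  cx <- (w + 1) / 2; cy <- (h + 1) / 2
  fov_r <- 0.48 * min(h, w)
  rad <- sqrt((X - cx)^2 + (Y - cy)^2)
  fov <- rad <= fov_r

  # Mucosal background: base color modulated by two texture scales.
  img <- array(0, c(h, w, 3))
  tex_coarse <- smooth_field(h, w, max(2, 0.06 * min(h, w)))
  tex_fine <- smooth_field(h, w, 1.2)
  tex <- 1 + 0.07 * tex_coarse + 0.035 * tex_fine
  for (c in 1:3) img[, , c] <- pal$mucosa[c] * tex

  # Faint background vasculature (all classes; never in the mask).
  n_bg_vessels <- 2L
  for (i in seq_len(n_bg_vessels)) {
    pts <- random_tube_endpoints(w, h, fov_r, cx, cy)
    sup <- tube_support(X, Y, pts$p0, pts$p1, pts$p2, sigma = 0.55 * spec$vessel_sigma)
    img <- blend_color(img, 0.25 * sup, c(150, 70, 70))
  }

  mask <- matrix(0L, h, w)
  lbl <- spec$class_label
  rr <- spec$lesion_radius_range

  if (lbl %in% c("Active bleeding", "Coagulated blood")) {
    col <- if (lbl == "Active bleeding") pal$active else pal$coagulated
    shrink <- if (lbl == "Coagulated blood") 0.8 else 1
    for (i in seq_len(spec$lesion_count)) {
      ctr <- random_point_in_fov(cx, cy, fov_r * 0.6)
      r0 <- runif(1, rr[1], rr[2]) * shrink
      sup <- blob_support(X, Y, ctr[1], ctr[2], r0)
      img <- blend_color(img, sup * 0.95, col)
      mask[sup > 0.5] <- 1L
    }
  } else if (lbl == "Vascular lesion") {
    for (i in seq_len(spec$vessel_count)) {
      pts <- random_tube_endpoints(w, h, fov_r, cx, cy)
      sup <- tube_support(X, Y, pts$p0, pts$p1, pts$p2, sigma = spec$vessel_sigma)
      img <- blend_color(img, sup * 0.9, pal$vessel)
      mask[sup > 0.45] <- 1L
    }
  } else if (lbl == "Esophagitis") {
    # Diffuse reddish streaks; the mask covers the streak support so that
    # segmentation has a target for every non-Normal class.
    for (i in seq_len(spec$lesion_count)) {
      pts <- random_tube_endpoints(w, h, fov_r, cx, cy)
      sup <- tube_support(X, Y, pts$p0, pts$p1, pts$p2,
                          sigma = runif(1, 1.8, 3.0) * spec$vessel_sigma)
      img <- blend_color(img, sup * 0.55, pal$streak)
      mask[sup > 0.35] <- 1L
    }
  } else if (lbl == "Ulcerative colitis") {
    for (i in seq_len(spec$lesion_count)) {
      ctr <- random_point_in_fov(cx, cy, fov_r * 0.55)
      r0 <- runif(1, rr[1], rr[2])
      outer <- blob_support(X, Y, ctr[1], ctr[2], r0)
      inner <- blob_support(X, Y, ctr[1], ctr[2], 0.62 * r0, wobble = 0.2)
      rim <- clip01(outer - inner)
      img <- blend_color(img, inner * 0.9, pal$uc_center)
      img <- blend_color(img, rim * 0.85, pal$uc_rim)
      mask[outer > 0.5] <- 1L
    }
  }

  # Illumination falloff: radial vignette plus a random linear gradient.
  if (spec$illumination_strength > 0) {
    ang <- runif(1, 0, 2 * pi)
    lin <- ((X - cx) * cos(ang) + (Y - cy) * sin(ang)) / fov_r
    L <- 1 - spec$illumination_strength *
      clip01(0.6 * (rad / fov_r)^2 + 0.4 * (lin + 1) / 2)
    for (c in 1:3) img[, , c] <- img[, , c] * L
  }

  # Specular highlights (saturated white spots, outside the mask label).
  for (i in seq_len(spec$specular_count)) {
    ctr <- random_point_in_fov(cx, cy, fov_r * 0.85)
    s <- runif(1, 0.8, 1.8)
    sup <- exp(-((X - ctr[1])^2 + (Y - ctr[2])^2) / (2 * s^2))
    img <- blend_color(img, sup, c(252, 250, 248))
  }

  # Sensor noise, FOV crop, clipping.
  if (spec$noise_sd > 0)
    img <- img + array(rnorm(h * w * 3, 0, spec$noise_sd), c(h, w, 3))
  img <- clip255(img)
  for (c in 1:3) img[, , c][!fov] <- 0
  mask[!fov] <- 0L

  structure(list(image = img, mask = mask, label = lbl, spec = spec),
            class = "wce_labeled_image")
}

random_point_in_fov <- function(cx, cy, rmax) {
  a <- runif(1, 0, 2 * pi); r <- sqrt(runif(1)) * rmax
  c(cx + r * cos(a), cy + r * sin(a))
}

random_tube_endpoints <- function(w, h, fov_r, cx, cy) {
  a <- runif(1, 0, 2 * pi)
  a2 <- a + pi + runif(1, -0.9, 0.9)
  p0 <- c(cx + 0.85 * fov_r * cos(a), cy + 0.85 * fov_r * sin(a))
  p2 <- c(cx + 0.85 * fov_r * cos(a2), cy + 0.85 * fov_r * sin(a2))
  mid <- (p0 + p2) / 2
  p1 <- mid + runif(2, -0.4, 0.4) * fov_r
  list(p0 = p0, p1 = p1, p2 = p2)
}

#' @export
print.wce_labeled_image <- function(x, ...) {
  cat(sprintf("<wce phantom> %dx%d  label=%s  lesion px=%d\n",
              nrow(x$mask), ncol(x$mask), x$label, sum(x$mask)))
  invisible(x)
}
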