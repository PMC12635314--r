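test_that("gaussian smoothing preserves constants, mean, and matches the kernel", {
  img <- constant_image(9, 9, 77)
  expect_equal(gaussian_smooth(img, 1), img, tolerance = 1e-12)

  img2 <- random_image(16, 16, seed = 1)
  sm <- gaussian_smooth(img2, 1.5)
  expect_lt(abs(mean(sm) - mean(img2)), 1e-6)

  # impulse response equals the directly evaluated normalized Gaussian
  imp <- array(0, c(9, 9, 3)); imp[5, 5, ] <- 1
  out <- gaussian_smooth(imp, 1)
  g <- exp(-((-4):4)^2 / 2); g <- g / sum(g)
  k2 <- outer(g, g)
  expect_lt(max(abs(out[, , 1] - k2)), 1e-9)
  # separability: the 2D response is the outer product of the 1D factors
  expect_equal(out[, , 1], outer(out[5, , 1], out[, 5, 1]) / out[5, 5, 1],
               tolerance = 1e-9)
  expect_error(gaussian_smooth(img2, 0), "positive")
})

test_that("gradient field matches finite differences", {
  img <- constant_image(8, 8, 9)
  g <- gradient_magnitude(img)
  expect_true(all(g$magnitude == 0))

  # ramp I = x: interior magnitude 1, orientation 0
  n <- 10
  ramp <- array(rep(rep(seq_len(n), each = n), 3), c(n, n, 3))
  gr <- gradient_magnitude(ramp)
  expect_equal(gr$magnitude[3:8, 3:8, 1], matrix(1, 6, 6))
  expect_equal(gr$orientation[3:8, 3:8, 1], matrix(0, 6, 6))

  # brute-force per-pixel differences on a random 8x8
  img2 <- random_image(8, 8, seed = 2)
  g2 <- gradient_magnitude(img2)
  for (ch in 1:3) {
    m <- img2[, , ch]
    for (y in c(1, 4, 8)) for (x in c(1, 5, 8)) {
      gx <- if (x == 1) m[y, 2] - m[y, 1]
            else if (x == 8) m[y, 8] - m[y, 7]
            else (m[y, x + 1] - m[y, x - 1]) / 2
      gy <- if (y == 1) m[2, x] - m[1, x]
            else if (y == 8) m[8, x] - m[7, x]
            else (m[y + 1, x] - m[y - 1, x]) / 2
      expect_equal(g2$magnitude[y, x, ch], sqrt(gx^2 + gy^2), tolerance = 1e-9)
    }
  }
  expect_error(gradient_magnitude(constant_image(2, 2, 1)), "3 x 3")
})

test_that("canny finds a closed one-pixel ring around a disk", {
  img <- disk_image(n = 41, radius = 12)
  ed <- canny_edges(img, sigma = 1.4, low_frac = 0.1, high_frac = 0.3)
  pix <- which(unclass(ed), arr.ind = TRUE)
  expect_gt(nrow(pix), 20)
  r <- sqrt((pix[, 1] - 21)^2 + (pix[, 2] - 21)^2)
  expect_true(all(abs(r - 12) <= 1.0))
  # edge pixels form a single closed (8-connected) component
  lab <- wcebleed:::label8(matrix(ed, 41, 41))
  expect_equal(max(lab), 1)
  # one pixel wide: no fully set 2x2 block
  e <- matrix(ed, 41, 41)
  blocks <- e[1:40, 1:40] & e[2:41, 1:40] & e[1:40, 2:41] & e[2:41, 2:41]
  expect_false(any(blocks))
  expect_error(canny_edges(img, low_frac = 0.4, high_frac = 0.2), "low_frac")
})

test_that("hysteresis keeps weak edges only when attached to strong ones", {
  # one vertical edge whose contrast fades from strong (top) to weak
  # (bottom) along its length, plus an isolated faint segment elsewhere;
  # the weak section survives only through its connection to the strong one
  n <- 32
  m <- matrix(20, n, n)
  right <- c(rep(220, 12), seq(220, 80, length.out = 8), rep(80, 12))
  for (y in 1:n) m[y, 17:n] <- right[y]
  m[28:30, 4] <- 26            # isolated faint blip
  img <- array(rep(m, 3), c(n, n, 3))
  ed <- canny_edges(img, sigma = 1, low_frac = 0.05, high_frac = 0.5)
  e <- matrix(ed, n, n)
  expect_true(any(e[5:12, 15:18]))    # strong section present
  expect_true(any(e[24:30, 15:18]))   # weak continuation retained
  expect_false(any(e[26:32, 2:6]))    # isolated faint segment removed
})

test_that("hough accumulator recovers an ideal line and bridges gaps", {
  # ideal line y = x on a 64x64 grid
  e <- matrix(FALSE, 64, 64)
  for (i in 1:64) e[i, i] <- TRUE
  hl <- hough_link(e, vote_frac = 0.9)
  expect_gt(length(hl$lines), 0)
  top <- hl$lines[[1]]
  expect_lt(abs(top$rho - 0), 1 + 1e-9)
  expect_lt(abs(top$theta - 3 * pi / 4), pi / 180 + 1e-9)

  # two collinear horizontal segments with a 4 px gap, gap_px = 5
  e2 <- matrix(FALSE, 20, 30)
  e2[10, 3:12] <- TRUE
  e2[10, 17:27] <- TRUE
  expect_equal(max(EBImage::bwlabel(e2)), 2)
  hl2 <- hough_link(e2, vote_frac = 0.5, gap_px = 5)
  expect_equal(max(EBImage::bwlabel(hl2$edges)), 1)
  # bridging never removes original edge pixels
  expect_true(all(hl2$edges[e2]))

  # blank map: zero lines, unchanged edges
  hb <- hough_link(matrix(FALSE, 8, 8))
  expect_length(hb$lines, 0)
  expect_equal(sum(hb$edges), 0)
  expect_error(hough_link(e2, rho_res = 0), "positive")
})

test_that("frangi vesselness obeys its limits and the scalar formula", {
  expect_equal(frangi_vesselness(constant_image(16, 16, 50)),
               constant_image(16, 16, 0) * 0)

  # scalar plug-in against an independently written expression
  v <- frangi_response(-2, -0.1, beta = 0.5, c_sensitivity = 1)
  expected <- exp(-(0.1 / 2)^2 / (2 * 0.25)) * (1 - exp(-(4 + 0.01) / 2))
  expect_lt(abs(v - expected), 1e-12)
  # strict mode uses S = sqrt(2) |lambda1|
  vs <- frangi_response(-2, -0.1, 0.5, 1, strict_paper_s = TRUE)
  expect_lt(abs(vs - exp(-(0.05)^2 / 0.5) * (1 - exp(-8 / 2))), 1e-12)
  expect_equal(frangi_response(0, 0, 0.5, 1), 0)

  # tube vs blob discrimination at matched brightness
  tub <- tube_image(n = 41, sigma = 2)
  dsk <- disk_image(n = 41, radius = 10)
  Vt <- frangi_vesselness(tub, frangi_config(sigma_scales = 2))
  Vd <- frangi_vesselness(dsk, frangi_config(sigma_scales = 2))
  centerline <- mean(Vt[21, 10:32, 1])
  Xd <- matrix(rep(seq_len(41), each = 41), 41, 41)
  Yd <- matrix(rep(seq_len(41), times = 41), 41, 41)
  # blob interior: inside the disk minus the 2-sigma band where the disk's
  # own edge curvature responds at the filter scale
  inside <- (Xd - 21)^2 + (Yd - 21)^2 <= (10 - 2 * 2)^2
  blob_mean <- mean(Vd[, , 1][inside])
  expect_gte(centerline, 5 * blob_mean)
  expect_true(all(Vt >= 0 & Vt < 1))
})

test_that("vesselness is invariant under 90-degree rotation", {
  tub <- tube_image(n = 33, sigma = 2)
  V <- frangi_vesselness(tub, frangi_config(sigma_scales = 2))
  rot <- function(a) {
    out <- a
    for (c in 1:3) out[, , c] <- t(a[, , c])[ncol(a[, , c]):1, ]
    out
  }
  V_rot_first <- frangi_vesselness(rot(tub), frangi_config(sigma_scales = 2))
  expect_lt(mean(abs(V_rot_first - rot(V))), 0.02 * max(mean(V), 1e-9))
})

test_that("enhancement blend honors its algebra", {
  E <- random_image(8, 8, seed = 3, lo = 0, hi = 200)
  V0 <- array(0, dim(E)); V1 <- array(1, dim(E))
  expect_equal(enhance(E, V0, alpha = 1), E * 0)
  expect_equal(enhance(E, V1, alpha = 0.7), E)
  Vr <- array(runif(length(E)), dim(E))
  expect_equal(enhance(E, Vr, alpha = 0), E)
  expect_error(enhance(E, array(0, c(4, 4, 3))), "mismatch")
})

test_that("enhance_image boosts linked edges and returns all intermediates", {
  it <- generate_phantom(phantom_spec("Vascular lesion", seed = 9))
  pre <- preprocess_image(it$image)
  en <- enhance_image(pre)
  expect_named(en, c("enhanced", "edges", "lines", "vesselness", "edge_image"))
  expect_true(all(en$enhanced >= 0 & en$enhanced <= 255))
  expect_true(all(en$vesselness >= 0 & en$vesselness < 1))
  boosted <- which(en$edges)
  if (length(boosted)) {
    ch <- en$edge_image[, , 1][boosted]
    expect_true(all(ch >= pre[, , 1][boosted] - 1e-9))
  }
})
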