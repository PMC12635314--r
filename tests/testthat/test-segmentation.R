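test_that("atrous convolution matches the brute-force dilated oracle", {
  set.seed(3)
  x <- array(runif(6 * 6 * 2), c(6, 6, 2))
  W <- matrix(rnorm(18 * 3, 0, 0.5), 18, 3)
  b <- rnorm(3)
  spec <- atrous_spec(rates = 2L, weights = list(W), bias = list(b))
  out <- atrous_features(x, spec)
  oracle <- dilated_conv_bruteforce(x, W, b, 2L)
  expect_lt(max(abs(out - oracle)), 1e-9)

  # rate 1 as well
  spec1 <- atrous_spec(rates = 1L, weights = list(W), bias = list(b))
  expect_lt(max(abs(atrous_features(x, spec1) -
                    dilated_conv_bruteforce(x, W, b, 1L))), 1e-9)
})

test_that("identity atrous kernel reproduces the input at any rate", {
  set.seed(4)
  x <- array(runif(9 * 9 * 3), c(9, 9, 3))
  W <- matrix(0, 27, 3)
  for (ci in 1:3) W[5 + 9 * (ci - 1), ci] <- 1  # center tap, channel ci
  for (r in c(1L, 2L, 4L)) {
    spec <- atrous_spec(rates = r, weights = list(W), bias = list(numeric(3)))
    out <- atrous_features(x, spec)
    expect_equal(out, x, tolerance = 1e-12)
    expect_equal(dim(out)[1:2], dim(x)[1:2])
  }
  # branch concatenation stacks widths
  spec2 <- atrous_spec(rates = c(1L, 2L), weights = list(W, W),
                       bias = list(numeric(3), numeric(3)))
  expect_equal(dim(atrous_features(x, spec2))[3], 6L)
})

test_that("softmax masks are normalized, shift-invariant and tie-broken low", {
  lg <- array(0, c(4, 4, 3))
  sm <- softmax_mask(lg)
  expect_true(all(abs(sm$probabilities - 1 / 3) < 1e-12))
  expect_true(all(sm$labels == 1L))  # exact ties resolve to class 1

  set.seed(5)
  lg2 <- array(rnorm(4 * 4 * 3), c(4, 4, 3))
  sm2 <- softmax_mask(lg2)
  expect_lt(max(abs(apply(sm2$probabilities, c(1, 2), sum) - 1)), 1e-6)
  sm3 <- softmax_mask(lg2 + 1000)
  expect_equal(sm2$probabilities, sm3$probabilities, tolerance = 1e-9)

  # scalar oracle: logits (2, 1, 0) at one pixel
  lg4 <- array(0, c(1, 1, 3)); lg4[1, 1, ] <- c(2, 1, 0)
  p <- softmax_mask(lg4)$probabilities[1, 1, ]
  expect_equal(p, exp(c(2, 1, 0)) / sum(exp(c(2, 1, 0))), tolerance = 1e-12)
  expect_error(softmax_mask(array(c(NA, 1), c(1, 1, 2))), "finite")
})

test_that("segmenter training is seed-deterministic and reduces the loss", {
  set.seed(6)
  items <- lapply(1:6, function(i)
    generate_phantom(phantom_spec(c("Active bleeding", "Normal")[(i %% 2) + 1],
                                  height = 32, width = 32, seed = 50 + i)))
  inputs <- lapply(items, function(it)
    wcebleed:::abind3(it$image / 255, it$mask * 0 + 0.5))
  masks <- lapply(items, function(it) it$mask)
  cfg <- train_config(epochs = 3L, batch_size = 3L, seed = 99)
  m1 <- train_segmenter(cfg = cfg, model = seg_model(seed = 1),
                        inputs = inputs, masks = masks,
                        select_operating_point = FALSE)
  m2 <- train_segmenter(cfg = cfg, model = seg_model(seed = 1),
                        inputs = inputs, masks = masks,
                        select_operating_point = FALSE)
  expect_identical(m1$loss_log, m2$loss_log)
  expect_identical(m1$params, m2$params)
  expect_lt(tail(m1$loss_log, 1), m1$loss_log[1])
})

test_that("segment is deterministic, typed, and guards untrained models", {
  it <- generate_phantom(phantom_spec("Active bleeding", height = 32,
                                      width = 32, seed = 77))
  x <- wcebleed:::abind3(it$image / 255, it$mask * 0)
  um <- seg_model(seed = 2)
  expect_error(segment(x, um), "untrained")
  tm <- train_segmenter(cfg = train_config(epochs = 2L, batch_size = 2L,
                                           seed = 3),
                        model = um, inputs = list(x), masks = list(it$mask),
                        select_operating_point = FALSE)
  s1 <- segment(x, tm); s2 <- segment(x, tm)
  expect_identical(s1$probabilities, s2$probabilities)
  expect_true(all(s1$labels %in% seq_along(tm$class_set)))
  expect_lt(max(abs(apply(s1$probabilities, c(1, 2), sum) - 1)), 1e-6)
  pm <- predict_mask(x, tm)
  expect_true(all(pm %in% c(0L, 1L)))
})

test_that("network gradients agree with central finite differences", {
  set.seed(8)
  m <- seg_model(in_channels = 2L, widths = c(3L, 4L, 5L, 3L), seed = 11)
  # nonzero biases keep pre-activations off the ReLU kink, where two-sided
  # differences disagree with any subgradient convention
  for (k in names(m$params))
    if (is.null(dim(m$params[[k]])))
      m$params[[k]] <- rnorm(length(m$params[[k]]), 0, 0.1)
  x <- array(runif(24 * 24 * 2), c(24, 24, 2))
  tgt <- matrix(sample(1:2, 576, TRUE), 24, 24)
  lossfun <- function(params) {
    m2 <- m; m2$params <- params
    wcebleed:::pixel_ce(wcebleed:::seg_forward(m2, x)$logits, tgt)$loss
  }
  fw <- wcebleed:::seg_forward(m, x)
  ce <- wcebleed:::pixel_ce(fw$logits, tgt)
  g <- wcebleed:::seg_backward(m, fw$cache, ce$grad)
  eps <- 1e-6
  for (k in names(m$params)) {
    i <- sample(length(m$params[[k]]), 1)
    pp <- m$params; pp[[k]][i] <- pp[[k]][i] + eps
    pm <- m$params; pm[[k]][i] <- pm[[k]][i] - eps
    num <- (lossfun(pp) - lossfun(pm)) / (2 * eps)
    expect_lt(abs(num - g[[k]][i]) / max(1e-8, abs(num) + abs(g[[k]][i])),
              1e-3)
  }
})

test_that("soft-Dice loss gradient is exact", {
  set.seed(9)
  lg <- array(rnorm(6 * 6 * 2), c(6, 6, 2))
  tg <- matrix(sample(1:2, 36, TRUE), 6, 6)
  sd0 <- wcebleed:::soft_dice_loss(lg, tg)
  eps <- 1e-6
  for (trial in 1:10) {
    i <- sample(length(lg), 1)
    lp <- lg; lp[i] <- lp[i] + eps
    lm <- lg; lm[i] <- lm[i] - eps
    num <- (wcebleed:::soft_dice_loss(lp, tg)$loss -
            wcebleed:::soft_dice_loss(lm, tg)$loss) / (2 * eps)
    expect_lt(abs(num - sd0$grad[i]), 1e-8)
  }
})
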