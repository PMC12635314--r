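test_that("a residual block with zeroed branch is the identity on ReLU inputs", {
  set.seed(1)
  x <- array(runif(6 * 6 * 4), c(6, 6, 4))  # non-negative, as after a ReLU
  wz <- matrix(0, 9 * 4, 4); bz <- numeric(4)
  blk <- wcebleed:::res_block_fwd(x, wz, bz, wz, bz)
  expect_equal(blk$out, x, tolerance = 1e-12)
})

test_that("one residual block matches a hand-composed conv + skip computation", {
  set.seed(2)
  x <- array(runif(4 * 4), c(4, 4, 1))
  wa <- matrix(rnorm(9, 0, 0.3), 9, 1); ba <- 0.05
  wb <- matrix(rnorm(9, 0, 0.3), 9, 1); bb <- -0.02
  blk <- wcebleed:::res_block_fwd(x, wa, ba, wb, bb, normalize = FALSE)
  # hand composition with an independent dilated-conv implementation
  c1 <- dilated_conv_bruteforce(x, wa, ba, 1L)
  r1 <- pmax(c1, 0)
  c2 <- dilated_conv_bruteforce(r1, wb, bb, 1L)
  expect_equal(blk$out, pmax(x + c2, 0), tolerance = 1e-9)
})

test_that("feature length is independent of input spatial size", {
  fe <- feature_extractor(d = 16L, width = 6L, blocks = 2L, seed = 3)
  h1 <- extract_features(random_image(64, 64, seed = 4), fe)
  h2 <- extract_features(random_image(96, 96, seed = 5), fe)
  expect_length(h1, 16L)
  expect_length(h2, 16L)
  # deterministic
  expect_identical(h1, extract_features(random_image(64, 64, seed = 4), fe))
})

test_that("mask_image zeroes background and falls back for empty masks", {
  img <- constant_image(4, 4, 10)
  m <- matrix(0L, 4, 4); m[2, 2] <- 1L
  out <- mask_image(img, m)
  expect_equal(out[2, 2, ], c(10, 10, 10))
  expect_equal(sum(out), 30)
  expect_equal(mask_image(img, matrix(0L, 4, 4)), img)
})

test_that("GNB estimates priors and moments, with a variance floor", {
  set.seed(6)
  f <- rbind(matrix(rnorm(40, 0), 20), matrix(rnorm(60, 5), 30))
  lab <- c(rep("a", 20), rep("b", 30))
  m <- fit_gnb(f, lab)
  expect_equal(m$priors, c(0.4, 0.6))
  expect_equal(m$means[1, 1], mean(f[1:20, 1]))
  expect_equal(m$vars[2, 1], mean((f[21:50, 1] - mean(f[21:50, 1]))^2),
               tolerance = 1e-12)

  # constant feature: floored variance, no division error
  f2 <- cbind(f, c(rep(1, 20), rnorm(30)))
  m2 <- fit_gnb(f2, lab)
  expect_equal(m2$vars[1, 3], m2$variance_floor)
  p <- gnb_posterior(m2, f2[1, ])
  expect_true(all(is.finite(p$probabilities)))
  expect_error(fit_gnb(f[1:21, , drop = FALSE], c(rep("a", 20), "b")),
               "at least 2")
})

test_that("GNB recovers known parameters from simulated features", {
  set.seed(7)
  k <- 6; n <- 1000; dd <- 4
  mu <- matrix(seq_len(k * dd), k, dd)
  sigma <- 1.5
  f <- do.call(rbind, lapply(1:k, function(i)
    matrix(rnorm(n * dd, rep(mu[i, ], each = n), sigma), n, dd)))
  lab <- rep(letters[1:k], each = n)
  m <- fit_gnb(f, lab)
  # at n = 1000 the standard error of each mean is sigma/sqrt(1000); the
  # typical (root-mean-square) estimation error sits well under 0.05 sigma,
  # while the worst of the 24 estimates can reach a few standard errors
  expect_lt(sqrt(mean((m$means - mu)^2)), 0.05 * sigma)
  expect_lt(max(abs(m$means - mu)), 0.15 * sigma)
  expect_lt(sqrt(mean((sqrt(m$vars) - sigma)^2)), 0.05 * sigma)
  expect_equal(m$priors, rep(1 / k, k))
})

test_that("posterior is normalized and matches the closed-form two-Gaussian case", {
  m <- structure(list(class_set = c("a", "b"), priors = c(0.5, 0.5),
                      means = matrix(c(0, 2), 2, 1),
                      vars = matrix(c(1, 1), 2, 1), variance_floor = 1e-12),
                 class = "wce_gnb_model")
  p1 <- gnb_posterior(m, 1)
  expect_equal(as.numeric(p1$probabilities), c(0.5, 0.5), tolerance = 1e-12)
  expect_equal(p1$label, "a")  # exact tie resolves to the lowest index
  p0 <- gnb_posterior(m, 0)
  lik <- dnorm(0, c(0, 2), 1)
  expect_equal(as.numeric(p0$probabilities), lik / sum(lik), tolerance = 1e-12)

  set.seed(8)
  h <- rnorm(1)
  expect_lt(abs(sum(gnb_posterior(m, h)$probabilities) - 1), 1e-9)

  # single-class degenerate model
  m1 <- structure(list(class_set = "only", priors = 1,
                       means = matrix(0, 1, 1), vars = matrix(1, 1, 1),
                       variance_floor = 1e-12), class = "wce_gnb_model")
  expect_equal(as.numeric(gnb_posterior(m1, 3)$probabilities), 1)
  expect_error(gnb_posterior(m, c(1, 2)), "dimension")
})

test_that("GNB agrees with an independent naive Bayes implementation", {
  skip_if_not_installed("e1071")
  set.seed(9)
  f <- rbind(matrix(rnorm(60, 0), 30), matrix(rnorm(60, 3), 30))
  lab <- rep(c("a", "b"), each = 30)
  ours <- fit_gnb(f, lab)
  theirs <- e1071::naiveBayes(data.frame(f), factor(lab))
  for (i in c(1, 15, 45)) {
    p_ours <- gnb_posterior(ours, f[i, ])$probabilities
    p_ref <- predict(theirs, data.frame(f)[i, ], type = "raw")[1, ]
    # e1071 uses n-1 variance; agreement is approximate but tight at n=30
    expect_equal(as.numeric(p_ours), as.numeric(p_ref), tolerance = 0.02)
  }
})

test_that("well-separated clusters are classified nearly perfectly", {
  set.seed(10)
  k <- 6; dd <- 8; sigma <- 1
  mu <- matrix(rnorm(k * dd), k, dd) * 10  # ||delta mu|| >> 6 sigma
  gen <- function(n) {
    f <- do.call(rbind, lapply(1:k, function(i)
      matrix(rnorm(n * dd, rep(mu[i, ], each = n), sigma), n, dd)))
    list(f = f, lab = rep(paste0("c", 1:k), each = n))
  }
  train <- gen(50); test <- gen(200)
  m <- fit_gnb(train$f, train$lab)
  preds <- apply(test$f, 1, function(h) gnb_predict(m, h)$label)
  expect_gte(mean(preds == test$lab), 0.99)
})

test_that("extractor warm-up reduces the training loss deterministically", {
  set.seed(11)
  imgs <- lapply(1:8, function(i) {
    base <- if (i %% 2) c(200, 40, 40) else c(60, 180, 60)
    im <- constant_image(16, 16, 0)
    for (c in 1:3) im[, , c] <- base[c] + matrix(rnorm(256, 0, 10), 16)
    wcebleed:::clip255(im)
  })
  labs <- rep(c("Active bleeding", "Normal"), 4)
  cfg <- train_config(epochs = 3L, batch_size = 4L, seed = 12)
  fe <- feature_extractor(width = 6L, d = 8L, blocks = 2L, seed = 13)
  t1 <- train_extractor(imgs, labs, fe, cfg)
  t2 <- train_extractor(imgs, labs, fe, cfg)
  expect_identical(t1$loss_log, t2$loss_log)
  expect_lt(tail(t1$loss_log, 1), t1$loss_log[1])
})
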