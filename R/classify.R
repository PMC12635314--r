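## Residual-feature / naive-Bayes fusion classification. A small residual
## convolutional extractor (conv blocks with identity skips, global average
## pooling to a fixed-length embedding) is warmed up with a temporary linear
## softmax head; the head is then discarded and a Gaussian naive Bayes
## model is fit on the pooled features. All posterior arithmetic stays in
## the log domain; the evidence term is handled by log-sum-exp and raw
## likelihood products are never formed.

#' Initialize the residual feature extractor
#'
#' A stem convolution followed by `blocks` residual blocks (two 3x3
#' convolutions with instance normalization and ReLU inside an identity
#' skip), spatial downsampling after the stem and mid-way, a 1x1 projection
#' to `d` channels and global average pooling. The embedding length `d` is
#' independent of the input spatial size.
#'
#' @param in_channels Input channels (3 for RGB).
#' @param d Embedding dimension (default 64).
#' @param width Channel width of the residual trunk (default 12).
#' @param blocks Number of residual blocks (default 4).
#' @param n_classes Classes for the warm-up head (default 6).
#' @param seed Seed for weight initialization.
#' @return A `wce_feature_extractor` list (untrained).
#' @export
feature_extractor <- function(in_channels = 3L, d = 64L, width = 12L,
                              blocks = 4L, n_classes = 6L, seed = 42L) {
  params <- with_seed(seed, {
    p <- list(w_stem = he_conv(in_channels, width), b_stem = numeric(width))
    for (i in seq_len(blocks)) {
      p[[paste0("w", i, "a")]] <- he_conv(width, width)
      p[[paste0("b", i, "a")]] <- numeric(width)
      p[[paste0("w", i, "b")]] <- he_conv(width, width)
      p[[paste0("b", i, "b")]] <- numeric(width)
    }
    p$w_proj <- matrix(rnorm(width * d, 0, sqrt(2 / width)), width, d)
    p$b_proj <- numeric(d)
    p$w_head <- matrix(rnorm(d * n_classes, 0, sqrt(1 / d)), d, n_classes)
    p$b_head <- numeric(n_classes)
    p
  })
  structure(list(params = params, in_channels = as.integer(in_channels),
                 d = as.integer(d), width = as.integer(width),
                 blocks = as.integer(blocks), n_classes = as.integer(n_classes),
                 seed = as.integer(seed), trained = FALSE),
            class = "wce_feature_extractor")
}

# One residual block: out = relu(x + conv_b(relu(norm(conv_a(x))))).
res_block_fwd <- function(x, wa, ba, wb, bb, normalize = TRUE) {
  ca <- conv_fwd(x, wa, ba)
  nm <- if (normalize) inorm_fwd(ca$out) else list(out = ca$out)
  ra <- relu_fwd(nm$out)
  cb <- conv_fwd(ra$out, wb, bb)
  rs <- relu_fwd(x + cb$out)
  list(out = rs$out, ca = ca, nm = nm, ra = ra, cb = cb, rs = rs,
       normalize = normalize)
}

res_block_bwd <- function(cc, dY) {
  ds <- relu_bwd(cc$rs, dY)
  bb <- conv_bwd(cc$cb, ds)
  dra <- relu_bwd(cc$ra, bb$dX)
  dna <- if (cc$normalize) inorm_bwd(cc$nm, dra) else dra
  ba <- conv_bwd(cc$ca, dna)
  list(dX = ds + ba$dX, dWa = ba$dW, dBa = ba$db, dWb = bb$dW, dBb = bb$db)
}

extractor_forward <- function(model, x, dropout_p = 0, train = FALSE) {
  p <- model$params
  cc <- list()
  cc$stem <- conv_fwd(x, p$w_stem, p$b_stem)
  cc$rs <- relu_fwd(cc$stem$out)
  cc$dn1 <- down2_fwd(cc$rs$out)
  h <- cc$dn1$out
  mid <- ceiling(model$blocks / 2)
  for (i in seq_len(model$blocks)) {
    cc[[paste0("blk", i)]] <- res_block_fwd(
      h, p[[paste0("w", i, "a")]], p[[paste0("b", i, "a")]],
      p[[paste0("w", i, "b")]], p[[paste0("b", i, "b")]])
    h <- cc[[paste0("blk", i)]]$out
    if (i == mid) {
      cc$dn2 <- down2_fwd(h)
      h <- cc$dn2$out
    }
  }
  cc$proj <- conv1x1_fwd(h, p$w_proj, p$b_proj)
  cc$pr <- relu_fwd(cc$proj$out)
  cc$gap <- gap_fwd(cc$pr$out)
  feat <- cc$gap$out
  cc$drop <- dropout_fwd(feat, dropout_p, train)
  cc$head <- linear_fwd(cc$drop$out, p$w_head, p$b_head)
  list(features = feat, logits = cc$head$out, cache = cc)
}

extractor_backward <- function(model, cc, dLogits) {
  g <- list()
  bh <- linear_bwd(cc$head, dLogits)
  g$w_head <- bh$dW; g$b_head <- bh$db
  dfeat <- dropout_bwd(cc$drop, bh$dX)
  dpr <- gap_bwd(cc$gap, dfeat)
  dproj <- relu_bwd(cc$pr, dpr)
  bp <- conv1x1_bwd(cc$proj, dproj)
  g$w_proj <- bp$dW; g$b_proj <- bp$db
  dh <- bp$dX
  mid <- ceiling(model$blocks / 2)
  for (i in rev(seq_len(model$blocks))) {
    if (i == mid) dh <- down2_bwd(cc$dn2, dh)
    bb <- res_block_bwd(cc[[paste0("blk", i)]], dh)
    g[[paste0("w", i, "a")]] <- bb$dWa; g[[paste0("b", i, "a")]] <- bb$dBa
    g[[paste0("w", i, "b")]] <- bb$dWb; g[[paste0("b", i, "b")]] <- bb$dBb
    dh <- bb$dX
  }
  drs <- down2_bwd(cc$dn1, dh)
  dstem <- relu_bwd(cc$rs, drs)
  bs <- conv_bwd(cc$stem, dstem)
  g$w_stem <- bs$dW; g$b_stem <- bs$db
  g
}

#' Restrict an image to its lesion region
#'
#' Zeroes background pixels. When the mask is empty (the Normal class) the
#' whole image is returned unchanged.
#'
#' @param img H x W x 3 image.
#' @param mask H x W 0/1 lesion mask.
#' @return Masked image.
#' @export
mask_image <- function(img, mask) {
  assert_image(img)
  if (sum(mask) == 0) return(img)
  for (c in 1:3) img[, , c] <- img[, , c] * (mask != 0)
  img
}

#' Extract the pooled feature vector of one (masked) image
#'
#' Deterministic forward pass through the residual extractor; input is
#' scaled to [0, 1] internally.
#'
#' @param masked_img H x W x 3 image on the 0-255 scale, background zeroed
#'   via [mask_image()] (whole image for empty masks).
#' @param model A [feature_extractor()].
#' @return Numeric feature vector of length `model$d`.
#' @export
extract_features <- function(masked_img, model) {
  assert_image(masked_img)
  if (length(masked_img) == 0L) stop("empty image")
  extractor_forward(model, masked_img / 255)$features
}

#' Warm up the feature extractor with a temporary linear head
#'
#' Supervised softmax cross-entropy training of the extractor plus linear
#' head by Adam with cosine decay; after warm-up the head is discarded and
#' only the pooled features are used downstream.
#'
#' @param images List of masked H x W x 3 images (0-255 scale).
#' @param labels Integer class indices (1-based) or class label strings.
#' @param model A [feature_extractor()].
#' @param cfg A [train_config()] (5 epochs is the pipeline default).
#' @param class_set Class label set defining the index order.
#' @param verbose Print per-epoch loss.
#' @return The trained model with `$loss_log`.
#' @export
train_extractor <- function(images, labels, model,
                            cfg = train_config(epochs = 5L),
                            class_set = wce_classes(), verbose = FALSE) {
  if (length(images) == 0L) stop("no training images")
  if (is.character(labels)) labels <- match(labels, class_set)
  if (any(is.na(labels))) stop("label outside class set")
  xs <- lapply(images, function(im) im / 255)
  n <- length(xs)
  params <- model$params
  st <- adam_init(params)
  total_steps <- cfg$epochs * ceiling(n / cfg$batch_size)
  step <- 0L
  loss_log <- numeric(cfg$epochs)
  with_seed(cfg$seed, {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      ep_losses <- c()
      for (b0 in seq(1, n, by = cfg$batch_size)) {
        idx <- ord[b0:min(b0 + cfg$batch_size - 1L, n)]
        acc <- zero_like(params)
        bl <- 0
        model$params <- params
        for (i in idx) {
          fw <- extractor_forward(model, xs[[i]], dropout_p = cfg$dropout,
                                  train = TRUE)
          ce <- vector_ce(fw$logits, labels[i])
          bl <- bl + ce$loss
          acc <- acc_grads(acc, extractor_backward(model, fw$cache, ce$grad))
        }
        acc <- lapply(acc, function(a) a / length(idx))
        lr <- cosine_lr(cfg$lr, step, total_steps)
        upd <- adam_step(params, acc, st, lr, cfg$weight_decay)
        params <- upd$params; st <- upd$st
        step <- step + 1L
        ep_losses <- c(ep_losses, bl / length(idx))
      }
      loss_log[ep] <- mean(ep_losses)
      if (verbose)
        message(sprintf("extractor epoch %d/%d  loss %.4f", ep, cfg$epochs,
                        loss_log[ep]))
    }
  })
  model$params <- params
  model$trained <- TRUE
  model$loss_log <- loss_log
  model
}

#' Fit a Gaussian naive Bayes model
#'
#' Maximum-likelihood estimation: priors are class frequencies; per-class
#' per-feature means and variances are sample moments, with variances
#' floored to avoid degeneracy for constant features.
#'
#' @param features Numeric matrix, one row per sample.
#' @param labels Class labels (character or factor), >= 2 samples per class.
#' @param variance_floor Lower bound on variances; default
#'   `1e-9 * max(feature variance)` (or 1e-12 if all variances vanish).
#' @param class_set Optional class order; defaults to the canonical WCE
#'   order for WCE labels, otherwise sorted unique labels.
#' @return A `wce_gnb_model` with `priors`, `means`, `vars`, `class_set`.
#' @export
fit_gnb <- function(features, labels, variance_floor = NULL,
                    class_set = NULL) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  if (nrow(features) != length(labels)) stop("features/labels length mismatch")
  if (is.null(class_set)) {
    u <- unique(labels)
    class_set <- if (all(u %in% WCE_CLASSES)) WCE_CLASSES[WCE_CLASSES %in% u]
                 else sort(u)
  }
  if (!all(labels %in% class_set)) stop("label outside class set")
  counts <- table(factor(labels, levels = class_set))
  if (any(counts < 2)) stop("every class needs at least 2 samples")
  k <- length(class_set); d <- ncol(features)
  means <- matrix(0, k, d); vars <- matrix(0, k, d)
  for (i in seq_len(k)) {
    xi <- features[labels == class_set[i], , drop = FALSE]
    means[i, ] <- colMeans(xi)
    vars[i, ] <- colMeans(sweep(xi, 2, means[i, ])^2)
  }
  if (is.null(variance_floor)) {
    vmax <- max(vars)
    variance_floor <- if (vmax > 0) 1e-9 * vmax else 1e-12
  }
  if (variance_floor <= 0) stop("variance floor must be positive")
  vars <- pmax(vars, variance_floor)
  structure(list(class_set = class_set,
                 priors = as.numeric(counts) / length(labels),
                 means = means, vars = vars,
                 variance_floor = variance_floor),
            class = "wce_gnb_model")
}

#' Class posterior under a Gaussian naive Bayes model
#'
#' Accumulates log prior plus per-feature Gaussian log likelihoods and
#' normalizes by log-sum-exp; the marginal evidence is never formed
#' explicitly, so well-separated classes cannot underflow.
#'
#' @param model A [fit_gnb()] model.
#' @param h Feature vector of the model's dimension.
#' @return A `wce_class_posterior`: list with `probabilities` (named, sums
#'   to 1) and `label` (argmax, ties to the lowest class index).
#' @export
gnb_posterior <- function(model, h) {
  if (length(h) != ncol(model$means)) stop("feature dimension mismatch")
  k <- length(model$class_set)
  logp <- numeric(k)
  for (i in seq_len(k)) {
    logp[i] <- log(model$priors[i]) +
      sum(stats::dnorm(h, model$means[i, ], sqrt(model$vars[i, ]), log = TRUE))
  }
  m <- max(logp)
  p <- exp(logp - m)
  p <- p / sum(p)
  names(p) <- model$class_set
  structure(list(probabilities = p,
                 label = model$class_set[which.max(p)]),
            class = "wce_class_posterior")
}

#' Predict the class of a feature vector
#'
#' Maximum-posterior decision; exact posterior ties resolve to the lowest
#' class index. The full posterior is returned alongside the label.
#'
#' @param model A [fit_gnb()] model.
#' @param h Feature vector.
#' @return List with `label` and `posterior` (named probabilities).
#' @export
gnb_predict <- function(model, h) {
  post <- gnb_posterior(model, h)
  list(label = post$label, posterior = post$probabilities)
}

#' Train the full fusion classifier
#'
#' Masks each training image to its lesion region, warms up the residual
#' extractor with a temporary linear head, then fits Gaussian naive Bayes
#' on the pooled features.
#'
#' @param images List of H x W x 3 images (0-255).
#' @param masks List of 0/1 lesion masks (ground truth at train time).
#' @param labels Class labels.
#' @param cfg A [train_config()] for the warm-up (default 5 epochs).
#' @param extractor Optional pre-built [feature_extractor()].
#' @param class_set Class label set.
#' @param verbose Print warm-up progress.
#' @return A `wce_classifier`: list with `extractor` and `gnb`.
#' @export
train_classifier <- function(images, masks, labels,
                             cfg = train_config(epochs = 5L),
                             extractor = NULL, class_set = wce_classes(),
                             verbose = FALSE) {
  masked <- mapply(mask_image, images, masks, SIMPLIFY = FALSE)
  if (is.null(extractor))
    extractor <- feature_extractor(n_classes = length(class_set),
                                   seed = cfg$seed)
  extractor <- train_extractor(masked, labels, extractor, cfg, class_set,
                               verbose = verbose)
  feats <- t(vapply(masked, function(im) extract_features(im, extractor),
                    numeric(extractor$d)))
  gnb <- fit_gnb(feats, labels, class_set = class_set[class_set %in% labels])
  structure(list(extractor = extractor, gnb = gnb, class_set = class_set),
            class = "wce_classifier")
}

#' Classify one image given its lesion mask
#'
#' @param img H x W x 3 image (0-255).
#' @param mask 0/1 lesion mask (predicted by [segment()] in the pipeline;
#'   empty masks fall back to the whole image).
#' @param clf A [train_classifier()] result.
#' @return List with `label` and `posterior`.
#' @export
classify_image <- function(img, mask, clf) {
  h <- extract_features(mask_image(img, mask), clf$extractor)
  gnb_predict(clf$gnb, h)
}
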