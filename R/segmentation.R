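## Compact encoder / dilated-spatial-pyramid / decoder segmenter, trained
## from scratch on CPU. The pyramid applies 3x3 convolutions at several
## dilation rates in parallel plus a global-pooling branch; the decoder
## bilinearly upsamples and fuses a full-resolution skip connection before
## the per-pixel softmax head. Binary {background, lesion} masks by default.

#' Atrous (dilated) convolution branch specification
#'
#' @param rates Integer dilation rates (default `c(1, 2, 4)`).
#' @param weights List (one per rate) of `(9 * Cin) x Cout` weight matrices
#'   in the package's tap-major layout (tap index fastest within channel;
#'   taps enumerate `(dy, dx)` in `{-1,0,1}^2` with `dy` fastest).
#' @param bias List (one per rate) of length-`Cout` bias vectors; zeros when
#'   omitted.
#' @return An `atrous_spec` list.
#' @export
atrous_spec <- function(rates = c(1L, 2L, 4L), weights, bias = NULL) {
  if (any(rates < 1)) stop("dilation rates must be >= 1")
  if (length(weights) != length(rates)) stop("one weight matrix per rate")
  if (is.null(bias)) bias <- lapply(weights, function(w) numeric(ncol(w)))
  structure(list(rates = as.integer(rates), weights = weights, bias = bias),
            class = "atrous_spec")
}

#' Apply parallel dilated 3x3 convolutions
#'
#' For each rate r the 3x3 kernel samples taps at offsets `r * {-1,0,1}^2`
#' with same-size zero padding; branch outputs are concatenated along the
#' channel axis. A kernel whose only nonzero tap is the center with weight 1
#' reproduces the input exactly at any rate.
#'
#' @param img H x W x C input array (a color image or feature stack).
#' @param spec An [atrous_spec()].
#' @return H x W x (sum of branch widths) feature stack.
#' @export
atrous_features <- function(img, spec) {
  x <- as_img3(img)
  outs <- lapply(seq_along(spec$rates), function(i)
    conv_fwd(x, spec$weights[[i]], spec$bias[[i]], spec$rates[i])$out)
  do.call(abind3, outs)
}

abind3 <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]])[1:2]
  ks <- vapply(parts, function(p) dim(as_img3(p))[3], integer(1))
  out <- array(0, c(d, sum(ks)))
  at <- 0L
  for (p in parts) {
    p <- as_img3(p)
    out[, , at + seq_len(dim(p)[3])] <- p
    at <- at + dim(p)[3]
  }
  out
}

#' Per-pixel softmax mask
#'
#' Numerically stabilized softmax over the class dimension; per-pixel
#' probabilities sum to 1 and the label map takes the argmax with ties
#' broken toward the lowest class index.
#'
#' @param logits H x W x K array of class scores (K >= 2).
#' @param class_set Optional class labels (length K).
#' @return A `wce_seg_mask` list with `probabilities`, `labels` (H x W
#'   integer, 1-based) and `class_set`.
#' @export
softmax_mask <- function(logits, class_set = NULL) {
  if (length(dim(logits)) != 3L || dim(logits)[3] < 2L)
    stop("logits must be H x W x K with K >= 2")
  if (any(!is.finite(logits))) stop("non-finite logits")
  p <- softmax_last(logits)
  d <- dim(p)
  pm <- matrix(p, prod(d[1:2]), d[3])
  labels <- matrix(max.col(pm, ties.method = "first"), d[1], d[2])
  if (is.null(class_set)) class_set <- paste0("class", seq_len(d[3]))
  structure(list(probabilities = p, labels = labels, class_set = class_set),
            class = "wce_seg_mask")
}

#' Initialize the segmentation model
#'
#' @param in_channels Input channels: 4 for the default enhanced-image +
#'   vesselness input, 3 for the literal color-only mode.
#' @param class_set Output classes (default binary background/lesion).
#' @param widths Channel widths `c(enc1, enc2, enc3, branch)`.
#' @param rates Pyramid dilation rates.
#' @param seed Seed for weight initialization.
#' @return A `wce_seg_model` list (untrained).
#' @export
seg_model <- function(in_channels = 4L,
                      class_set = c("background", "lesion"),
                      widths = c(12L, 24L, 32L, 16L),
                      rates = c(1L, 2L, 4L), seed = 42L) {
  k <- length(class_set)
  w1 <- widths[1]; w2 <- widths[2]; w3 <- widths[3]; wb <- widths[4]
  params <- with_seed(seed, {
    p <- list(
      w_enc1 = he_conv(in_channels, w1), b_enc1 = numeric(w1),
      w_enc2 = he_conv(w1, w2), b_enc2 = numeric(w2),
      w_enc3 = he_conv(w2, w3), b_enc3 = numeric(w3))
    for (i in seq_along(rates)) {
      p[[paste0("w_aspp", i)]] <- he_conv(w3, wb)
      p[[paste0("b_aspp", i)]] <- numeric(wb)
    }
    p$w_pool <- matrix(rnorm(w3 * wb, 0, sqrt(2 / w3)), w3, wb)
    p$b_pool <- numeric(wb)
    nb <- wb * (length(rates) + 1L)
    p$w_fuse <- matrix(rnorm(nb * w3, 0, sqrt(2 / nb)), nb, w3)
    p$b_fuse <- numeric(w3)
    p$w_dec <- he_conv(w3 + w1, w2)
    p$b_dec <- numeric(w2)
    p$w_head <- matrix(rnorm(w2 * k, 0, sqrt(2 / w2)), w2, k)
    p$b_head <- numeric(k)
    p
  })
  structure(list(params = params, in_channels = as.integer(in_channels),
                 class_set = class_set, widths = widths,
                 rates = as.integer(rates), seed = as.integer(seed),
                 trained = FALSE, loss_log = numeric(0),
                 operating_point = list(threshold = 0.5, min_size = 0L)),
            class = "wce_seg_model")
}

# Forward pass; returns logits and (when grad=TRUE) the caches needed for
# backprop. dropout_p > 0 only during training.
seg_forward <- function(model, x, dropout_p = 0, train = FALSE) {
  p <- model$params
  cc <- list()
  cc$c1 <- conv_fwd(x, p$w_enc1, p$b_enc1); cc$r1 <- relu_fwd(cc$c1$out)
  cc$c2 <- conv_fwd(cc$r1$out, p$w_enc2, p$b_enc2); cc$r2 <- relu_fwd(cc$c2$out)
  cc$d2 <- down2_fwd(cc$r2$out)
  cc$c3 <- conv_fwd(cc$d2$out, p$w_enc3, p$b_enc3); cc$r3 <- relu_fwd(cc$c3$out)
  cc$d3 <- down2_fwd(cc$r3$out)
  branches <- list()
  for (i in seq_along(model$rates)) {
    ci <- conv_fwd(cc$d3$out, p[[paste0("w_aspp", i)]],
                   p[[paste0("b_aspp", i)]], model$rates[i])
    ri <- relu_fwd(ci$out)
    cc[[paste0("ca", i)]] <- ci; cc[[paste0("ra", i)]] <- ri
    branches[[i]] <- ri$out
  }
  cc$gp <- gap_fwd(cc$d3$out)
  cc$pl <- linear_fwd(cc$gp$out, p$w_pool, p$b_pool)
  cc$plr <- relu_fwd(cc$pl$out)
  dlow <- dim(cc$d3$out)
  pool_map <- array(rep(cc$plr$out, each = dlow[1] * dlow[2]),
                    c(dlow[1], dlow[2], length(cc$plr$out)))
  branches[[length(branches) + 1L]] <- pool_map
  cat_low <- do.call(abind3, branches)
  cc$fuse <- conv1x1_fwd(cat_low, p$w_fuse, p$b_fuse)
  cc$fr <- relu_fwd(cc$fuse$out)
  cc$drop <- dropout_fwd(cc$fr$out, dropout_p, train)
  hw <- dim(x)[1:2]
  cc$A <- interp_matrix(hw[1], dlow[1]); cc$B <- interp_matrix(hw[2], dlow[2])
  cc$up <- upsample_fwd(cc$drop$out, cc$A, cc$B)
  cat_full <- abind3(cc$up$out, cc$r1$out)
  cc$dec <- conv_fwd(cat_full, p$w_dec, p$b_dec)
  cc$dr <- relu_fwd(cc$dec$out)
  cc$head <- conv1x1_fwd(cc$dr$out, p$w_head, p$b_head)
  list(logits = cc$head$out, cache = cc)
}

seg_backward <- function(model, cc, dLogits) {
  p <- model$params
  g <- list()
  bh <- conv1x1_bwd(cc$head, dLogits)
  g$w_head <- bh$dW; g$b_head <- bh$db
  dd <- relu_bwd(cc$dr, bh$dX)
  bd <- conv_bwd(cc$dec, dd)
  g$w_dec <- bd$dW; g$b_dec <- bd$db
  w3 <- model$widths[3]; w1 <- model$widths[1]
  d_up <- bd$dX[, , seq_len(w3), drop = FALSE]
  d_skip <- bd$dX[, , w3 + seq_len(w1), drop = FALSE]
  d_drop <- upsample_bwd(cc$up, d_up)
  d_fr <- dropout_bwd(cc$drop, d_drop)
  d_fuse <- relu_bwd(cc$fr, d_fr)
  bf <- conv1x1_bwd(cc$fuse, d_fuse)
  g$w_fuse <- bf$dW; g$b_fuse <- bf$db
  wb <- model$widths[4]
  nr <- length(model$rates)
  d_d3 <- cc$d3$out * 0
  for (i in seq_len(nr)) {
    d_bi <- bf$dX[, , (i - 1L) * wb + seq_len(wb), drop = FALSE]
    d_ci <- relu_bwd(cc[[paste0("ra", i)]], d_bi)
    bi <- conv_bwd(cc[[paste0("ca", i)]], d_ci)
    g[[paste0("w_aspp", i)]] <- bi$dW; g[[paste0("b_aspp", i)]] <- bi$db
    d_d3 <- d_d3 + bi$dX
  }
  d_pool_map <- bf$dX[, , nr * wb + seq_len(wb), drop = FALSE]
  d_plr <- apply(d_pool_map, 3, sum)
  d_pl <- relu_bwd(cc$plr, d_plr)
  bl <- linear_bwd(cc$pl, d_pl)
  g$w_pool <- bl$dW; g$b_pool <- bl$db
  d_d3 <- d_d3 + gap_bwd(cc$gp, bl$dX)
  d_r3 <- down2_bwd(cc$d3, d_d3)
  d_c3 <- relu_bwd(cc$r3, d_r3)
  b3 <- conv_bwd(cc$c3, d_c3)
  g$w_enc3 <- b3$dW; g$b_enc3 <- b3$db
  d_r2 <- down2_bwd(cc$d2, b3$dX)
  d_c2 <- relu_bwd(cc$r2, d_r2)
  b2 <- conv_bwd(cc$c2, d_c2)
  g$w_enc2 <- b2$dW; g$b_enc2 <- b2$db
  d_c1 <- relu_bwd(cc$r1, b2$dX + d_skip)
  b1 <- conv_bwd(cc$c1, d_c1)
  g$w_enc1 <- b1$dW; g$b_enc1 <- b1$db
  g
}

#' Training configuration
#'
#' Defaults follow the pipeline's training recipe: Adam at learning rate
#' 1e-3 with cosine decay, batch size 16, weight decay 1e-4, dropout 0.5.
#'
#' @param lr Initial learning rate.
#' @param batch_size Mini-batch size (gradients averaged over the batch).
#' @param epochs Training epochs.
#' @param weight_decay L2 penalty coefficient on weight matrices.
#' @param dropout Dropout probability applied after the pyramid fusion
#'   (segmenter) or before the linear head (classifier warm-up).
#' @param seed Seed controlling shuffling, dropout and initialization use.
#' @return A `train_config` list.
#' @export
train_config <- function(lr = 1e-3, batch_size = 16L, epochs = 20L,
                         weight_decay = 1e-4, dropout = 0.5, seed = 42L) {
  if (lr <= 0) stop("learning rate must be positive")
  if (batch_size < 1) stop("batch size must be >= 1")
  structure(list(lr = lr, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), weight_decay = weight_decay,
                 dropout = dropout, seed = as.integer(seed)),
            class = "train_config")
}

#' Build the segmenter input stack for one image
#'
#' Runs preprocessing and the enhancement chain, then stacks the enhanced
#' image (3 channels) with the channel-mean vesselness map as a 4th
#' channel, all scaled to [0, 1]. With `paper_literal = TRUE` only the 3
#' enhanced channels are used.
#'
#' @param img Raw H x W x 3 image on the 0-255 scale.
#' @param pre_cfg A [preprocess_config()].
#' @param enh_cfg An [enhance_config()].
#' @param paper_literal Drop the vesselness channel.
#' @return H x W x 4 (or x 3) float array in [0, 1].
#' @export
seg_input <- function(img, pre_cfg = preprocess_config(),
                      enh_cfg = enhance_config(), paper_literal = FALSE) {
  pre <- preprocess_image(img, pre_cfg)
  en <- enhance_image(pre, enh_cfg)
  x <- en$enhanced / 255
  if (paper_literal) return(x)
  vmean <- (en$vesselness[, , 1] + en$vesselness[, , 2] +
            en$vesselness[, , 3]) / 3
  abind3(x, vmean)
}

#' Train the segmenter
#'
#' Adam on per-pixel cross-entropy with cosine learning-rate decay;
#' deterministic loss trajectory under a fixed seed. Inputs can be given
#' directly (list of H x W x C arrays plus list of masks) or as a manifest
#' data frame with `image`/`mask` paths, in which case [seg_input()] is
#' applied to the train split.
#'
#' @param manifest Manifest data frame (from [build_dataset()]) or `NULL`
#'   when `inputs`/`masks` are supplied.
#' @param cfg A [train_config()].
#' @param model A [seg_model()].
#' @param inputs,masks Optional precomputed input stacks and 0/1 masks.
#' @param pre_cfg,enh_cfg Stage configurations used when reading from a
#'   manifest.
#' @param class_weighting Weight the per-pixel cross-entropy by the square
#'   root of the inverse class frequency over the training masks (default
#'   `TRUE`); lesion pixels are rare, and unweighted training can collapse
#'   to the all-background solution, while full inverse-frequency weighting
#'   over-produces false positives.
#' @param select_operating_point After training, choose the lesion
#'   probability threshold and minimum connected-component size that
#'   maximize mean Dice on (a subsample of) the training set; stored in the
#'   model and applied by [predict_mask()] (default `TRUE`; binary models
#'   only).
#' @param dice_weight Weight of an additional per-image soft-Dice term on
#'   the foreground probability (binary models only, default 0.5); the
#'   total loss is `cross_entropy + dice_weight * (1 - soft Dice)`. Set to
#'   0 for pure cross-entropy.
#' @param verbose Print per-epoch loss.
#' @return The trained model with `$loss_log` (per-epoch mean training loss)
#'   and `$operating_point`.
#' @export
train_segmenter <- function(manifest = NULL, cfg = train_config(), model,
                            inputs = NULL, masks = NULL,
                            pre_cfg = preprocess_config(),
                            enh_cfg = enhance_config(),
                            class_weighting = TRUE,
                            select_operating_point = TRUE,
                            dice_weight = 0.5, verbose = FALSE) {
  if (is.null(inputs)) {
    if (is.null(manifest)) stop("either a manifest or inputs must be given")
    tr <- manifest[manifest$split == "train", , drop = FALSE]
    if (nrow(tr) == 0L) stop("empty train split")
    inputs <- lapply(tr$image, function(p)
      seg_input(read_image(p), pre_cfg, enh_cfg,
                paper_literal = model$in_channels == 3L))
    masks <- lapply(tr$mask, read_mask)
  }
  if (length(inputs) == 0L) stop("empty train split")
  k <- length(model$class_set)
  targets <- lapply(masks, function(m) {
    t <- m + 1L
    if (any(t > k)) stop("mask labels exceed model class set")
    t
  })
  cw <- NULL
  if (isTRUE(class_weighting)) {
    counts <- numeric(k)
    for (t in targets) counts <- counts + tabulate(t, nbins = k)
    counts <- pmax(counts, 1)
    cw <- sqrt(sum(counts) / (k * counts))
  }
  n <- length(inputs)
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
          fw <- seg_forward(model, inputs[[i]], dropout_p = cfg$dropout,
                            train = TRUE)
          ce <- pixel_ce(fw$logits, targets[[i]], cw)
          grad <- ce$grad
          li <- ce$loss
          if (dice_weight > 0 && k == 2L) {
            sd <- soft_dice_loss(fw$logits, targets[[i]])
            grad <- grad + dice_weight * sd$grad
            li <- li + dice_weight * sd$loss
          }
          bl <- bl + li
          g <- seg_backward(model, fw$cache, grad)
          acc <- acc_grads(acc, g)
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
        message(sprintf("epoch %d/%d  loss %.4f", ep, cfg$epochs, loss_log[ep]))
    }
  })
  model$params <- params
  model$trained <- TRUE
  model$loss_log <- loss_log
  if (isTRUE(select_operating_point) && k == 2L) {
    probs <- lapply(seq_len(n), function(i)
      softmax_last(seg_forward(model, inputs[[i]], dropout_p = 0,
                               train = FALSE)$logits)[, , 2])
    best <- model$operating_point; best_dice <- -1
    for (thr in seq(0.4, 0.9, by = 0.05)) {
      for (ms in c(0L, 8L, 16L, 24L, 40L)) {
        dd <- mean(vapply(seq_len(n), function(j)
          dice_coefficient(postprocess_mask(probs[[j]] >= thr, ms),
                           masks[[j]]), numeric(1)))
        if (dd > best_dice + 1e-12) {
          best_dice <- dd
          best <- list(threshold = thr, min_size = ms)
        }
      }
    }
    model$operating_point <- best
    if (verbose)
      message(sprintf("operating point: threshold %.2f, min size %d (train Dice %.3f)",
                      best$threshold, best$min_size, best_dice))
  }
  model
}

# Threshold post-processing shared by operating-point selection and
# predict_mask: drop small components, then fill interior holes (lesions
# are solid regions; specular pixels can punch holes into predictions).
postprocess_mask <- function(pm, min_size) {
  pm <- filter_small_components(pm, min_size)
  if (any(pm)) pm <- EBImage::fillHull(pm) > 0
  pm
}

# Drop connected components smaller than min_size pixels from a logical mask.
filter_small_components <- function(pm, min_size) {
  if (min_size <= 0 || !any(pm)) return(pm)
  lab <- EBImage::bwlabel(pm)
  sizes <- table(lab[lab > 0])
  keep <- as.integer(names(sizes)[sizes >= min_size])
  matrix(lab %in% keep, nrow(pm))
}

#' Predict the binary lesion mask for one image
#'
#' Applies the model's trained operating point: lesion pixels are those
#' whose lesion probability reaches the stored threshold; connected
#' components smaller than the stored minimum size are removed (suppressing
#' speckle false positives on lesion-free tissue) and interior holes are
#' filled (lesions are solid regions).
#'
#' @param img Input stack or raw image as in [segment()].
#' @param model A trained binary [seg_model()].
#' @param pre_cfg,enh_cfg Stage configurations used when `img` is raw.
#' @return H x W 0/1 integer lesion mask.
#' @export
predict_mask <- function(img, model, pre_cfg = preprocess_config(),
                         enh_cfg = enhance_config()) {
  if (length(model$class_set) != 2L)
    stop("predict_mask needs a binary model; use segment() for multi-class")
  sm <- segment(img, model, pre_cfg, enh_cfg)
  op <- model$operating_point
  pm <- postprocess_mask(sm$probabilities[, , 2] >= op$threshold, op$min_size)
  matrix(as.integer(pm), nrow(pm))
}

#' Segment one image with a trained model
#'
#' Deterministic inference (no dropout). Accepts either a prepared input
#' stack matching the model's input channels or a raw color image, in which
#' case [seg_input()] is applied first.
#'
#' @param img Input stack (H x W x `in_channels`, values in [0, 1]) or a raw
#'   0-255 color image.
#' @param model A trained [seg_model()].
#' @param pre_cfg,enh_cfg Stage configurations used when `img` is raw.
#' @return A [softmax_mask()] result over the model's class set.
#' @export
segment <- function(img, model, pre_cfg = preprocess_config(),
                    enh_cfg = enhance_config()) {
  if (!isTRUE(model$trained)) stop("model is untrained; train it first")
  x <- as_img3(img)
  if (dim(x)[3] != model$in_channels) {
    if (dim(x)[3] == 3L && max(x) > 1.5)
      x <- seg_input(x, pre_cfg, enh_cfg,
                     paper_literal = model$in_channels == 3L)
    else stop("input channels do not match the model")
  }
  fw <- seg_forward(model, x, dropout_p = 0, train = FALSE)
  softmax_mask(fw$logits, model$class_set)
}
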