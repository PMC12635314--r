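## Optional residual refinement network for the preprocessing stage: eight
## 3x3 stride-1 convolutions with ReLU between them, predicting an additive
## correction (output = input + correction). The final layer is
## zero-initialized, so the untrained network is exactly the identity; the
## deterministic equalize + Retinex path is canonical and this refinement
## is opt-in.

#' Initialize the refinement network
#'
#' Eight 3x3 stride-1 convolution layers with ReLU activations between
#' them and a zero-initialized final layer feeding a residual (additive)
#' output, so an untrained model maps any image to itself.
#'
#' @param channels Hidden channel width (default 8).
#' @param seed Seed for weight initialization.
#' @return A `wce_refine_model` list.
#' @export
refine_model <- function(channels = 8L, seed = 42L) {
  n_layers <- 8L
  params <- with_seed(seed, {
    p <- list()
    cin <- 3L
    for (i in seq_len(n_layers)) {
      cout <- if (i == n_layers) 3L else channels
      w <- if (i == n_layers) matrix(0, 9 * cin, cout) else he_conv(cin, cout)
      p[[paste0("w", i)]] <- w
      p[[paste0("b", i)]] <- numeric(cout)
      cin <- cout
    }
    p
  })
  structure(list(params = params, channels = as.integer(channels),
                 n_layers = n_layers, seed = as.integer(seed),
                 trained = FALSE, loss_log = numeric(0)),
            class = "wce_refine_model")
}

refine_forward <- function(model, x) {
  p <- model$params
  cc <- list()
  h <- x
  for (i in seq_len(model$n_layers)) {
    cc[[paste0("c", i)]] <- conv_fwd(h, p[[paste0("w", i)]],
                                     p[[paste0("b", i)]])
    h <- cc[[paste0("c", i)]]$out
    if (i < model$n_layers) {
      cc[[paste0("r", i)]] <- relu_fwd(h)
      h <- cc[[paste0("r", i)]]$out
    }
  }
  list(out = x + h, cache = cc)
}

refine_backward <- function(model, cc, dOut) {
  g <- list()
  dh <- dOut
  for (i in rev(seq_len(model$n_layers))) {
    if (i < model$n_layers) dh <- relu_bwd(cc[[paste0("r", i)]], dh)
    b <- conv_bwd(cc[[paste0("c", i)]], dh)
    g[[paste0("w", i)]] <- b$dW; g[[paste0("b", i)]] <- b$db
    dh <- b$dX
  }
  g
}

#' Apply the refinement network to an image
#'
#' @param img H x W x 3 image on the 0-255 scale.
#' @param model A [refine_model()], trained or not (untrained is the
#'   identity).
#' @return Refined image, clipped to [0, 255].
#' @export
refine_apply <- function(img, model) {
  assert_image(img)
  clip255(refine_forward(model, img / 255)$out * 255)
}

#' Train the refinement network on (degraded, clean) image pairs
#'
#' Minimizes mean squared error between refined degraded images and their
#' clean targets, by Adam with cosine decay.
#'
#' @param degraded,clean Lists of H x W x 3 images on the 0-255 scale.
#' @param model A [refine_model()].
#' @param cfg A [train_config()].
#' @param verbose Print per-epoch loss.
#' @return Trained model with `$loss_log`.
#' @export
refine_train <- function(degraded, clean, model = refine_model(),
                         cfg = train_config(epochs = 10L, dropout = 0),
                         verbose = FALSE) {
  if (length(degraded) != length(clean) || length(degraded) == 0L)
    stop("need matching non-empty lists of image pairs")
  xs <- lapply(degraded, function(im) im / 255)
  ys <- lapply(clean, function(im) im / 255)
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
          fw <- refine_forward(model, xs[[i]])
          err <- fw$out - ys[[i]]
          bl <- bl + mean(err^2)
          acc <- acc_grads(acc, refine_backward(model, fw$cache,
                                                2 * err / length(err)))
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
        message(sprintf("refine epoch %d/%d  mse %.6f", ep, cfg$epochs,
                        loss_log[ep]))
    }
  })
  model$params <- params
  model$trained <- TRUE
  model$loss_log <- loss_log
  model
}
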