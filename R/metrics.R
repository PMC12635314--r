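## Evaluation metrics: image quality (PSNR, SSIM, mean gradient magnitude,
## color fidelity), segmentation overlap (Dice, mean pixel accuracy, pixel
## sensitivity/specificity) and classification quality (confusion matrix,
## accuracy, macro one-vs-rest sensitivity/specificity, rank-statistic AUC,
## Cohen's kappa).

#' Image-quality report
#'
#' PSNR is `10 log10(255^2 / MSE)`, capped at 100 dB for identical images.
#' SSIM uses the standard constants (K1 = 0.01, K2 = 0.03, L = 255) with an
#' 11 x 11 Gaussian window (sigma 1.5) on luminance. GM is the mean gradient
#' magnitude of the test image's luminance (edge sharpness). CFI is the mean
#' per-pixel cosine similarity between the RGB vectors of test and
#' reference, in [0, 1] for non-negative images; pixels that are black in
#' both images count as perfectly matched.
#'
#' @param test,reference H x W x 3 images on the 0-255 scale, same shape.
#' @return List with `psnr` (dB), `ssim`, `gm`, `cfi`.
#' @export
image_quality <- function(test, reference) {
  assert_image(test); assert_image(reference)
  if (!all(dim(test) == dim(reference))) stop("shape mismatch")
  mse <- mean((test - reference)^2)
  psnr <- if (mse == 0) 100 else min(100, 10 * log10(255^2 / mse))
  yt <- luminance(test); yr <- luminance(reference)
  ssim <- ssim_luminance(yt, yr)
  g <- gradient_channel(yt)
  gm <- mean(sqrt(g$gx^2 + g$gy^2))
  tm <- matrix(test, ncol = 3); rm_ <- matrix(reference, ncol = 3)
  num <- rowSums(tm * rm_)
  den <- sqrt(rowSums(tm^2)) * sqrt(rowSums(rm_^2))
  cos_sim <- ifelse(den == 0, 1, num / pmax(den, 1e-12))
  list(psnr = psnr, ssim = ssim, gm = gm, cfi = mean(cos_sim))
}

ssim_luminance <- function(x, y, K1 = 0.01, K2 = 0.03, L = 255,
                           sigma = 1.5, radius = 5L) {
  C1 <- (K1 * L)^2; C2 <- (K2 * L)^2
  g <- gaussian_kernel_1d(sigma, radius)
  w <- function(m) sep_conv_channel(m, g, g)
  mx <- w(x); my <- w(y)
  vx <- w(x * x) - mx^2; vy <- w(y * y) - my^2
  cxy <- w(x * y) - mx * my
  s <- ((2 * mx * my + C1) * (2 * cxy + C2)) /
    ((mx^2 + my^2 + C1) * (vx + vy + C2))
  mean(s)
}

#' Dice similarity coefficient of two binary masks
#'
#' `2 |P intersect T| / (|P| + |T|)`; defined as 1 when both masks are empty
#' (perfect agreement on absence).
#'
#' @param pred,truth Binary masks (0/1 or logical), same shape.
#' @return Dice coefficient in [0, 1].
#' @export
dice_coefficient <- function(pred, truth) {
  p <- pred != 0; t <- truth != 0
  denom <- sum(p) + sum(t)
  if (denom == 0) return(1)
  2 * sum(p & t) / denom
}

#' Segmentation report
#'
#' Per-class Dice and the mean, mean pixel accuracy (per-class pixel recall
#' averaged over classes), and pixelwise sensitivity/specificity treating
#' the highest class index as foreground in the binary case.
#'
#' @param pred Label matrix (1-based class indices) or a
#'   [softmax_mask()] result.
#' @param truth Label matrix of the same shape and class set (for binary
#'   masks, 0/1 is accepted and shifted to 1/2).
#' @param n_classes Number of classes; inferred when `pred` is a mask object.
#' @return List with `dice` (per class), `mean_dice`, `mpa`, `sensitivity`,
#'   `specificity`.
#' @export
segmentation_report <- function(pred, truth, n_classes = NULL) {
  if (inherits(pred, "wce_seg_mask")) {
    n_classes <- length(pred$class_set)
    pred <- pred$labels
  }
  if (is.logical(truth) || min(truth) == 0) truth <- truth + 1L
  if (is.logical(pred) || min(pred) == 0) pred <- pred + 1L
  if (!all(dim(pred) == dim(truth))) stop("shape mismatch")
  if (is.null(n_classes)) n_classes <- max(pred, truth)
  if (max(truth) > n_classes || max(pred) > n_classes)
    stop("labels exceed the class set")
  dice <- numeric(n_classes); recall <- numeric(n_classes)
  for (k in seq_len(n_classes)) {
    pk <- pred == k; tk <- truth == k
    dice[k] <- dice_coefficient(pk, tk)
    recall[k] <- if (sum(tk) == 0) 1 else sum(pk & tk) / sum(tk)
  }
  fg <- n_classes
  tp <- sum(pred == fg & truth == fg); fn <- sum(pred != fg & truth == fg)
  tn <- sum(pred != fg & truth != fg); fp <- sum(pred == fg & truth != fg)
  list(dice = dice, mean_dice = mean(dice), mpa = mean(recall),
       sensitivity = if (tp + fn == 0) 1 else tp / (tp + fn),
       specificity = if (tn + fp == 0) 1 else tn / (tn + fp))
}

# One-vs-rest AUC by the rank statistic (Mann-Whitney), ties counted 1/2.
auc_rank <- function(scores, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification report and confusion matrix
#'
#' Confusion counts (rows = true, columns = predicted), accuracy, macro
#' one-vs-rest sensitivity and specificity, macro one-vs-rest AUC via the
#' rank statistic (ties contribute 1/2), and Cohen's kappa
#' `(p_o - p_e) / (1 - p_e)`.
#'
#' @param truths,preds Class label vectors of equal length.
#' @param scores Optional posterior matrix (rows sum to 1, one column per
#'   class in `class_set` order) for AUC.
#' @param class_set Class label set; defaults as in [fit_gnb()].
#' @return List with `confusion` (K x K matrix) and `report` (accuracy,
#'   sensitivity, specificity, auc, kappa).
#' @export
classification_report <- function(truths, preds, scores = NULL,
                                  class_set = NULL) {
  truths <- as.character(truths); preds <- as.character(preds)
  if (length(truths) != length(preds)) stop("length mismatch")
  if (is.null(class_set)) {
    u <- unique(c(truths, preds))
    class_set <- if (all(u %in% WCE_CLASSES)) WCE_CLASSES[WCE_CLASSES %in% u]
                 else sort(u)
  }
  if (!all(c(truths, preds) %in% class_set)) stop("label outside class set")
  tf <- factor(truths, levels = class_set)
  pf <- factor(preds, levels = class_set)
  confusion <- table(true = tf, predicted = pf)
  n <- length(truths)
  accuracy <- sum(diag(confusion)) / n
  k <- length(class_set)
  sens <- numeric(k); spec <- numeric(k)
  for (i in seq_len(k)) {
    tp <- confusion[i, i]; fn <- sum(confusion[i, -i])
    fp <- sum(confusion[-i, i]); tn <- n - tp - fn - fp
    sens[i] <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
    spec[i] <- if (tn + fp == 0) NA_real_ else tn / (tn + fp)
  }
  auc <- NA_real_
  if (!is.null(scores)) {
    scores <- as.matrix(scores)
    if (nrow(scores) != n || ncol(scores) != k)
      stop("scores must be n x K in class_set order")
    aucs <- vapply(seq_len(k), function(i)
      auc_rank(scores[, i], truths == class_set[i]), numeric(1))
    auc <- mean(aucs, na.rm = TRUE)
  }
  p_o <- accuracy
  p_e <- sum(rowSums(confusion) * colSums(confusion)) / n^2
  kappa <- if (p_e == 1) 1 else (p_o - p_e) / (1 - p_e)
  list(confusion = unclass(confusion),
       report = list(accuracy = accuracy,
                     sensitivity = mean(sens, na.rm = TRUE),
                     specificity = mean(spec, na.rm = TRUE),
                     auc = auc, kappa = kappa))
}
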