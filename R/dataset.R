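## Dataset assembly: write seeded phantoms to disk and build a stratified
## train/val/test manifest with k-fold assignments on the train+val portion.
## Every phantom carries a synthetic patient id; augmented variants inherit
## the id of their source image so that variants of one frame never straddle
## splits.

#' Build a stratified synthetic phantom dataset on disk
#'
#' Generates `n_per_class` phantoms for each requested class, writes images
#' and masks as PNG under `out_dir`, and returns (and writes) a manifest CSV
#' stratified by class. The default split is 80-10-10 with 5-fold
#' cross-validation folds assigned on the train+val portion; an 80/20 split
#' is available by passing `split_fracs = c(0.8, 0, 0.2)`. Per class, the
#' test and validation sizes are rounded down and the remainder goes to
#' train. Deterministic under `seed`.
#'
#' @param n_per_class Integer (applied to all classes) or named integer
#'   vector mapping class label to count.
#' @param split_fracs Length-3 numeric `(train, val, test)` summing to 1.
#' @param k_folds Number of cross-validation folds over train+val.
#' @param seed Integer seed.
#' @param out_dir Output directory (created if missing).
#' @param size Phantom side length in pixels.
#' @param augment_cfg Optional [augment_config()]; when supplied, augmented
#'   variants of every train-split image are generated and appended to the
#'   train split (inheriting patient id and fold).
#' @param classes Class labels to include (default all six).
#' @return The manifest as a data frame (also written to
#'   `out_dir/manifest.csv`) with columns image, mask, label, split, fold,
#'   patient_id, seed.
#' @export
build_dataset <- function(n_per_class, split_fracs = c(0.8, 0.1, 0.1),
                          k_folds = 5L, seed = 1L, out_dir,
                          size = 64L, augment_cfg = NULL,
                          classes = wce_classes()) {
  if (abs(sum(split_fracs) - 1) > 1e-9)
    stop("split_fracs must sum to 1")
  if (any(split_fracs < 0)) stop("split_fracs must be non-negative")
  if (length(n_per_class) == 1L && is.null(names(n_per_class)))
    n_per_class <- stats::setNames(rep(n_per_class, length(classes)), classes)
  if (!all(classes %in% names(n_per_class)))
    stop("n_per_class must cover every class")
  if (any(n_per_class[classes] < k_folds))
    stop("need at least k_folds phantoms per class")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  img_dir <- file.path(out_dir, "images"); msk_dir <- file.path(out_dir, "masks")
  dir.create(img_dir, showWarnings = FALSE); dir.create(msk_dir, showWarnings = FALSE)

  rows <- list()
  pid <- 0L
  for (cl in classes) {
    n <- n_per_class[[cl]]
    n_test <- floor(n * split_fracs[3])
    n_val <- floor(n * split_fracs[2])
    n_train <- n - n_val - n_test
    split <- c(rep("train", n_train), rep("val", n_val), rep("test", n_test))
    # Shuffle which phantom lands in which split, deterministically.
    ord <- with_seed(stage_seed(seed, paste0("split/", cl)), sample.int(n))
    split <- split[order(ord)]
    trainval_idx <- which(split != "test")
    folds <- rep(NA_integer_, n)
    folds[trainval_idx] <- rep_len(seq_len(k_folds), length(trainval_idx))

    for (i in seq_len(n)) {
      pid <- pid + 1L
      item_seed <- stage_seed(seed, sprintf("phantom/%s/%d", cl, i))
      spec <- phantom_spec(cl, height = size, width = size, seed = item_seed)
      item <- generate_phantom(spec)
      base <- sprintf("%s_%04d", gsub("[^A-Za-z]", "", cl), i)
      ipath <- file.path(img_dir, paste0(base, ".png"))
      mpath <- file.path(msk_dir, paste0(base, ".png"))
      write_image(item$image, ipath)
      write_mask(item$mask, mpath)
      rows[[length(rows) + 1L]] <- data.frame(
        image = ipath, mask = mpath, label = cl, split = split[i],
        fold = folds[i], patient_id = sprintf("P%05d", pid),
        seed = item_seed, stringsAsFactors = FALSE)
      if (!is.null(augment_cfg) && split[i] == "train" &&
          augment_cfg$variants_per_image > 0L) {
        vars <- augment(item, augment_cfg,
                        seed = stage_seed(seed, paste0("aug/", base)))
        for (v in seq_along(vars)) {
          vbase <- sprintf("%s_aug%d", base, v)
          vip <- file.path(img_dir, paste0(vbase, ".png"))
          vmp <- file.path(msk_dir, paste0(vbase, ".png"))
          write_image(vars[[v]]$image, vip)
          write_mask(vars[[v]]$mask, vmp)
          rows[[length(rows) + 1L]] <- data.frame(
            image = vip, mask = vmp, label = cl, split = "train",
            fold = folds[i], patient_id = sprintf("P%05d", pid),
            seed = item_seed, stringsAsFactors = FALSE)
        }
      }
    }
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  manifest
}

#' Read a dataset manifest CSV
#'
#' @param path Path to a manifest.csv written by [build_dataset()].
#' @return Manifest data frame.
#' @export
read_manifest <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
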