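#' Read an RGB image to the 0-255 float scale
#'
#' Reads a PNG (8- or 16-bit) and returns an H x W x 3 array of float
#' intensities on the 0-255 scale, the internal carrier for all pipeline
#' stages. Grayscale files are replicated across channels; alpha is dropped.
#'
#' @param path Path to a PNG file.
#' @return H x W x 3 numeric array with values in [0, 255].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("no such image file: ", path)
  a <- png::readPNG(path)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3L), c(dim(a), 3L))
  if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]
  if (dim(a)[3] == 1L) a <- array(rep(a, 3L), c(dim(a)[1:2], 3L))
  a * 255
}

#' Write an RGB image from the 0-255 float scale
#'
#' Values are clipped to [0, 255] and quantized to 8 bits only here, at file
#' write; all in-memory processing stays in float.
#'
#' @param img H x W x 3 numeric array on the 0-255 scale.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  assert_image(img)
  png::writePNG(clip255(img) / 255, path)
  invisible(path)
}

#' Read a binary lesion mask
#'
#' Masks are stored as 0/255 PNG; any pixel above half intensity is foreground.
#'
#' @param path Path to a mask PNG.
#' @return H x W integer matrix of 0/1.
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop("no such mask file: ", path)
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- a[, , 1]
  m <- matrix(as.integer(a > 0.5), nrow(a), ncol(a))
  m
}

#' Write a binary lesion mask as 0/255 PNG
#'
#' @param mask H x W matrix; nonzero means lesion.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask != 0), nrow(mask), ncol(mask)), path)
  invisible(path)
}
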