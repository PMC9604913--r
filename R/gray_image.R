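#' Coerce to a single-channel intensity image
#'
#' A gray image is a plain numeric matrix of finite intensities, row = image
#' row, column = image column. Multi-channel arrays (H x W x 3 or H x W x 4)
#' are converted to luma with ITU-R BT.601 weights; an alpha channel is
#' dropped. Intensities loaded from files are in `[0, 1]`, but any finite
#' range is accepted so that photometric transforms `a*I + b` remain valid
#' inputs.
#'
#' @param x numeric matrix, or numeric array with 1, 3 or 4 channels on the
#'   third dimension.
#' @return numeric matrix of intensities.
#' @export
as_gray_image <- function(x) {
  if (is.array(x) && length(dim(x)) == 3L) {
    nc <- dim(x)[3L]
    if (nc == 1L) {
      x <- x[, , 1L]
    } else if (nc %in% c(3L, 4L)) {
      x <- rgb_to_gray(x)
    } else {
      stop("cannot interpret array with ", nc, " channels as a gray image")
    }
  }
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("a gray image must be a numeric matrix")
  }
  if (nrow(x) < 1L || ncol(x) < 1L) stop("image must have at least one pixel")
  if (!all(is.finite(x))) stop("image intensities must be finite")
  storage.mode(x) <- "double"
  x
}

#' Convert an RGB(A) array to luma
#'
#' Uses ITU-R BT.601 weights (0.299, 0.587, 0.114). Alpha is ignored.
#'
#' @param x numeric array H x W x {3,4}.
#' @return numeric matrix H x W.
#' @export
rgb_to_gray <- function(x) {
  stopifnot(is.array(x), length(dim(x)) == 3L, dim(x)[3L] >= 3L)
  0.299 * x[, , 1L] + 0.587 * x[, , 2L] + 0.114 * x[, , 3L]
}

#' Rotate an image counter-clockwise by quarter turns
#'
#' @param img numeric matrix.
#' @param k number of 90-degree counter-clockwise turns.
#' @return rotated matrix.
#' @export
rot90_image <- function(img, k = 1L) {
  k <- as.integer(k) %% 4L
  for (i in seq_len(k)) {
    img <- t(img)[rev(seq_len(ncol(img))), , drop = FALSE]
  }
  img
}

#' Mirror an image horizontally (reverse columns)
#'
#' @param img numeric matrix.
#' @return flipped matrix.
#' @export
flip_image <- function(img) {
  img[, ncol(img):1L, drop = FALSE]
}

# Reflect (half-sample symmetric) index into 1..n, valid for any integer i.
reflect_index <- function(i, n) {
  j <- (i - 1L) %% (2L * n)
  j <- ifelse(j < 0L, j + 2L * n, j)
  ifelse(j >= n, 2L * n - 1L - j, j) + 1L
}

#' Pad an image spatially
#'
#' `reflect` is half-sample symmetric padding (the edge pixel is repeated as
#' the first mirrored sample); `zero` pads with zeros.
#'
#' @param img numeric matrix.
#' @param p pad width in pixels on every side.
#' @param mode `"reflect"` or `"zero"`.
#' @return matrix of size (H + 2p) x (W + 2p).
#' @export
pad_image <- function(img, p, mode = c("reflect", "zero")) {
  mode <- match.arg(mode)
  p <- as.integer(p)
  stopifnot(p >= 0L)
  if (p == 0L) return(img)
  h <- nrow(img); w <- ncol(img)
  if (mode == "reflect") {
    ri <- reflect_index(seq.int(1L - p, h + p), h)
    ci <- reflect_index(seq.int(1L - p, w + p), w)
    img[ri, ci, drop = FALSE]
  } else {
    out <- matrix(0, h + 2L * p, w + 2L * p)
    out[(p + 1L):(p + h), (p + 1L):(p + w)] <- img
    out
  }
}
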