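#' Dense SIFT descriptor configuration
#'
#' Geometry and normalization of the per-pixel descriptor. The defaults give
#' the classic 128-dimensional SIFT layout: an `N = 8` pixel neighborhood,
#' a 4 x 4 cell grid, and an 8-bin gradient-orientation histogram per cell
#' (4 * 4 * 8 = 128 values).
#'
#' The `N x N` window around pixel `(r, c)` covers rows `r - N/2 .. r + N/2 - 1`
#' and the same range of columns, so its geometric center sits at the
#' half-pixel `(r - 0.5, c - 0.5)`. Gradient samples are binned with soft
#' linear assignment to the two nearest orientation bins (bin centers at
#' `k * 2*pi/bins`) and bilinear spatial assignment to neighboring cells;
#' `soft_binning = FALSE` switches both to hard nearest assignment.
#'
#' @param patch_size neighborhood side `N` in pixels (default 8).
#' @param cells_per_side cell grid side (default 4); must divide `patch_size`.
#' @param orientation_bins histogram bins per cell (default 8).
#' @param stride descriptor grid spacing in pixels (default 1 = every pixel).
#' @param boundary_mode `"reflect"` (half-sample symmetric) or `"zero"` image
#'   padding, so border pixels get descriptors too.
#' @param normalization `"l2_clip"` (L2-normalize, clip entries at
#'   `clip_threshold`, renormalize — the classic SIFT scheme), `"l2"`, or
#'   `"none"`.
#' @param clip_threshold clip value for `"l2_clip"` (default 0.2).
#' @param orientation_normalized if `TRUE`, cyclically shift every cell's
#'   orientation bins so the window's dominant orientation bin comes first
#'   (a light per-pixel orientation normalization; default `FALSE`, the dense
#'   SIFT convention).
#' @param soft_binning use soft orientation/spatial assignment (default
#'   `TRUE`).
#' @return object of class `dense_sift_config`.
#' @export
dense_sift_config <- function(patch_size = 8L,
                              cells_per_side = 4L,
                              orientation_bins = 8L,
                              stride = 1L,
                              boundary_mode = c("reflect", "zero"),
                              normalization = c("l2_clip", "l2", "none"),
                              clip_threshold = 0.2,
                              orientation_normalized = FALSE,
                              soft_binning = TRUE) {
  cfg <- list(
    patch_size = as.integer(patch_size),
    cells_per_side = as.integer(cells_per_side),
    orientation_bins = as.integer(orientation_bins),
    stride = as.integer(stride),
    boundary_mode = match.arg(boundary_mode),
    normalization = match.arg(normalization),
    clip_threshold = as.numeric(clip_threshold),
    orientation_normalized = isTRUE(orientation_normalized),
    soft_binning = isTRUE(soft_binning)
  )
  cfg$descriptor_dim <- cfg$cells_per_side^2L * cfg$orientation_bins
  if (cfg$patch_size < cfg$cells_per_side ||
      cfg$patch_size %% cfg$cells_per_side != 0L) {
    stop("patch_size must be a positive multiple of cells_per_side")
  }
  if (cfg$orientation_bins < 1L) stop("orientation_bins must be >= 1")
  if (cfg$stride < 1L) stop("stride must be >= 1")
  if (!(cfg$clip_threshold > 0 && cfg$clip_threshold <= 1)) {
    stop("clip_threshold must be in (0, 1]")
  }
  class(cfg) <- "dense_sift_config"
  cfg
}

#' @export
print.dense_sift_config <- function(x, ...) {
  cat(sprintf(
    "dense SIFT config: N=%d, %dx%d cells, %d bins (M=%d), stride %d, %s boundary, %s normalization\n",
    x$patch_size, x$cells_per_side, x$cells_per_side, x$orientation_bins,
    x$descriptor_dim, x$stride, x$boundary_mode, x$normalization))
  invisible(x)
}

#' Image gradients by central differences
#'
#' Gradients `dx` (along columns) and `dy` (along rows) by central
#' differences; borders use the padded image per `boundary_mode`. Orientation
#' is `atan2(dy, dx)` mapped to `[0, 2*pi)` and set to 0 where the magnitude
#' vanishes.
#'
#' @param img gray image matrix.
#' @param boundary_mode `"reflect"` or `"zero"`.
#' @return list with `magnitude`, `orientation`, `dx`, `dy` matrices the same
#'   size as `img`.
#' @export
image_gradients <- function(img, boundary_mode = c("reflect", "zero")) {
  boundary_mode <- match.arg(boundary_mode)
  img <- as_gray_image(img)
  h <- nrow(img); w <- ncol(img)
  if (boundary_mode == "reflect" && (h < 3L || w < 3L)) {
    stop("degenerate input: image must be at least 3x3 for reflect boundaries")
  }
  p <- pad_image(img, 1L, boundary_mode)
  dx <- (p[2L:(h + 1L), 3L:(w + 2L), drop = FALSE] -
           p[2L:(h + 1L), 1L:w, drop = FALSE]) / 2
  dy <- (p[3L:(h + 2L), 2L:(w + 1L), drop = FALSE] -
           p[1L:h, 2L:(w + 1L), drop = FALSE]) / 2
  magnitude <- sqrt(dx^2 + dy^2)
  orientation <- atan2(dy, dx) %% (2 * pi)
  orientation[magnitude == 0] <- 0
  list(magnitude = magnitude, orientation = orientation, dx = dx, dy = dy)
}

# Gradient fields of the image padded so that every window sample of every
# pixel (including borders) is defined: pad by N/2 + 1, central differences,
# drop the outermost ring. Returned fields cover original coordinates
# -N/2+1 .. H+N/2 (offset N/2).
padded_gradients <- function(img, cfg) {
  p <- cfg$patch_size %/% 2L + 1L
  pi_ <- pad_image(img, p, cfg$boundary_mode)
  hp <- nrow(pi_); wp <- ncol(pi_)
  dx <- (pi_[2L:(hp - 1L), 3L:wp, drop = FALSE] -
           pi_[2L:(hp - 1L), 1L:(wp - 2L), drop = FALSE]) / 2
  dy <- (pi_[3L:hp, 2L:(wp - 1L), drop = FALSE] -
           pi_[1L:(hp - 2L), 2L:(wp - 1L), drop = FALSE]) / 2
  magnitude <- sqrt(dx^2 + dy^2)
  orientation <- atan2(dy, dx) %% (2 * pi)
  orientation[magnitude == 0] <- 0
  list(magnitude = magnitude, orientation = orientation,
       offset = cfg$patch_size %/% 2L)
}

#' Descriptor channel index
#'
#' Fixed layout of the `M`-vector: row-major over cells, orientation bin
#' fastest. All arguments are 0-based; the returned index is 0-based.
#'
#' @param cell_row,cell_col 0-based cell coordinates.
#' @param bin 0-based orientation bin.
#' @param cfg a [dense_sift_config()].
#' @return 0-based channel index in `[0, M)`.
#' @export
channel_index <- function(cell_row, cell_col, bin, cfg) {
  (cell_row * cfg$cells_per_side + cell_col) * cfg$orientation_bins + bin
}

#' Inverse of [channel_index()]
#'
#' @param idx 0-based channel index (vectorized).
#' @param cfg a [dense_sift_config()].
#' @return data.frame with 0-based `cell_row`, `cell_col`, `bin`.
#' @export
channel_layout <- function(idx, cfg) {
  bin <- idx %% cfg$orientation_bins
  cell <- idx %/% cfg$orientation_bins
  data.frame(cell_row = cell %/% cfg$cells_per_side,
             cell_col = cell %% cfg$cells_per_side,
             bin = bin)
}

# Normalize one descriptor vector per cfg$normalization.
normalize_descriptor <- function(v, cfg, eps = 1e-12) {
  if (cfg$normalization == "none") return(v)
  n <- sqrt(sum(v * v))
  if (n < eps) return(v * 0)
  v <- v / n
  if (cfg$normalization == "l2_clip") {
    v <- pmin(v, cfg$clip_threshold)
    n2 <- sqrt(sum(v * v))
    v <- if (n2 < eps) v * 0 else v / n2
  }
  v
}

# Cyclic shift of orientation bins so the dominant bin (summed over cells,
# ties to the lowest index) becomes bin 0. The dominant bin is the lowest
# index within a small relative tolerance of the maximum, so that exact
# mathematical ties (e.g. from mirror-padded borders) resolve identically
# in the loop and vectorized paths. desc is a raw (unnormalized) descriptor.
orientation_normalize_descriptor <- function(desc, cfg) {
  nb <- cfg$orientation_bins; nc2 <- cfg$cells_per_side^2L
  bins_tot <- rowSums(matrix(desc, nrow = nb, ncol = nc2))
  mx <- max(bins_tot)
  m <- which(bins_tot >= mx - (1e-9 * mx + 1e-12))[1L] - 1L
  if (m == 0L) return(desc)
  shifted <- (seq_len(nb) - 1L + m) %% nb           # new bin b <- old bin b+m
  take <- rep((0:(nc2 - 1L)) * nb, each = nb) + rep(shifted + 1L, nc2)
  desc[take]
}

#' Reference per-pixel SIFT descriptor (nested-loop computation)
#'
#' Computes the descriptor of the `N x N` neighborhood of pixel
#' `(row, col)` by explicit loops over window samples, cells and bins. This
#' is the package's reference path: deliberately simple and independent of
#' the vectorized [compute_sift_image()], which must agree with it
#' elementwise.
#'
#' @param img gray image matrix.
#' @param row,col 1-based pixel coordinates inside the image.
#' @param cfg a [dense_sift_config()].
#' @return numeric vector of length `cfg$descriptor_dim` in
#'   [channel_index()] order.
#' @export
descriptor_at <- function(img, row, col, cfg = dense_sift_config()) {
  img <- as_gray_image(img)
  stopifnot(row >= 1L, row <= nrow(img), col >= 1L, col <= ncol(img))
  if (cfg$boundary_mode == "reflect" && (nrow(img) < 3L || ncol(img) < 3L)) {
    stop("degenerate input: image must be at least 3x3 for reflect boundaries")
  }
  g <- padded_gradients(img, cfg)
  half <- cfg$patch_size %/% 2L
  cell <- cfg$patch_size %/% cfg$cells_per_side
  nb <- cfg$orientation_bins
  ncs <- cfg$cells_per_side
  desc <- numeric(cfg$descriptor_dim)
  for (dy in seq.int(-half, half - 1L)) {
    for (dx in seq.int(-half, half - 1L)) {
      m <- g$magnitude[row + dy + g$offset, col + dx + g$offset]
      if (m == 0) next
      th <- g$orientation[row + dy + g$offset, col + dx + g$offset]
      t <- th * nb / (2 * pi)
      # spatial cell coordinates of this sample (continuous, cell units)
      ur <- (dy + half + 0.5) / cell - 0.5
      uc <- (dx + half + 0.5) / cell - 0.5
      if (cfg$soft_binning) {
        i0 <- floor(ur); fr <- ur - i0
        j0 <- floor(uc); fc <- uc - j0
        b0 <- floor(t) %% nb; fb <- t - floor(t)
        for (ci in c(i0, i0 + 1)) {
          wr <- if (ci == i0) 1 - fr else fr
          if (ci < 0 || ci > ncs - 1 || wr == 0) next
          for (cj in c(j0, j0 + 1)) {
            wc <- if (cj == j0) 1 - fc else fc
            if (cj < 0 || cj > ncs - 1 || wc == 0) next
            for (bb in c(b0, (b0 + 1) %% nb)) {
              wb <- if (bb == b0) 1 - fb else fb
              k <- channel_index(ci, cj, bb, cfg) + 1L
              desc[k] <- desc[k] + m * wr * wc * wb
            }
          }
        }
      } else {
        ci <- (dy + half) %/% cell
        cj <- (dx + half) %/% cell
        bb <- floor(t + 0.5) %% nb
        k <- channel_index(ci, cj, bb, cfg) + 1L
        desc[k] <- desc[k] + m
      }
    }
  }
  if (cfg$orientation_normalized) {
    desc <- orientation_normalize_descriptor(desc, cfg)
  }
  normalize_descriptor(desc, cfg)
}

#' Compute the SIFT image of a gray image
#'
#' Maps a single-channel image to its SIFT image: an
#' `H' x W' x M` array holding one dense SIFT descriptor per stride-spaced
#' pixel (`H' = ceiling(H / stride)`, `M = 128` by default), with the same
#' spatial size as the input at stride 1. Constant regions produce all-zero
#' descriptors. The computation is fully vectorized; it agrees with the
#' nested-loop reference [descriptor_at()] to floating-point roundoff.
#'
#' @param img gray image matrix.
#' @param cfg a [dense_sift_config()].
#' @return array of class `sift_image` with attributes `source_shape` and
#'   `config`.
#' @export
compute_sift_image <- function(img, cfg = dense_sift_config()) {
  img <- as_gray_image(img)
  h <- nrow(img); w <- ncol(img)
  if (cfg$boundary_mode == "reflect" && (h < 3L || w < 3L)) {
    stop("degenerate input: image must be at least 3x3 for reflect boundaries")
  }
  g <- padded_gradients(img, cfg)
  off <- g$offset
  half <- cfg$patch_size %/% 2L
  cell <- cfg$patch_size %/% cfg$cells_per_side
  nb <- cfg$orientation_bins
  ncs <- cfg$cells_per_side
  M <- cfg$descriptor_dim
  gr <- seq.int(1L, h, cfg$stride)
  gc <- seq.int(1L, w, cfg$stride)
  hh <- length(gr); ww <- length(gc)
  npos <- hh * ww
  pos <- seq_len(npos)

  # per-pixel orientation bin weights on the padded fields
  tfield <- g$orientation * nb / (2 * pi)
  if (cfg$soft_binning) {
    b0f <- floor(tfield)
    j0 <- b0f %% nb
    fb <- tfield - b0f
    m0 <- g$magnitude * (1 - fb)
    m1 <- g$magnitude * fb
    j1 <- (j0 + 1) %% nb
  } else {
    j0 <- floor(tfield + 0.5) %% nb
    m0 <- g$magnitude
  }

  acc <- numeric(npos * M)
  for (dy in seq.int(-half, half - 1L)) {
    rows <- gr + dy + off
    ur <- (dy + half + 0.5) / cell - 0.5
    for (dx in seq.int(-half, half - 1L)) {
      cols <- gc + dx + off
      uc <- (dx + half + 0.5) / cell - 0.5
      if (cfg$soft_binning) {
        i0 <- floor(ur); fr <- ur - i0
        k0 <- floor(uc); fc <- uc - k0
        cr <- c(i0, i0 + 1); wr <- c(1 - fr, fr)
        cc <- c(k0, k0 + 1); wc <- c(1 - fc, fc)
        J0 <- j0[rows, cols, drop = FALSE]
        J1 <- j1[rows, cols, drop = FALSE]
        M0 <- m0[rows, cols, drop = FALSE]
        M1 <- m1[rows, cols, drop = FALSE]
        for (a in 1:2) {
          if (cr[a] < 0 || cr[a] > ncs - 1 || wr[a] == 0) next
          for (b in 1:2) {
            if (cc[b] < 0 || cc[b] > ncs - 1 || wc[b] == 0) next
            wgt <- wr[a] * wc[b]
            base <- (cr[a] * ncs + cc[b]) * nb
            t0 <- pos + (base + as.vector(J0)) * npos
            acc[t0] <- acc[t0] + wgt * as.vector(M0)
            t1 <- pos + (base + as.vector(J1)) * npos
            acc[t1] <- acc[t1] + wgt * as.vector(M1)
          }
        }
      } else {
        ci <- (dy + half) %/% cell
        cj <- (dx + half) %/% cell
        base <- (ci * ncs + cj) * nb
        J0 <- j0[rows, cols, drop = FALSE]
        M0 <- m0[rows, cols, drop = FALSE]
        t0 <- pos + (base + as.vector(J0)) * npos
        acc[t0] <- acc[t0] + as.vector(M0)
      }
    }
  }

  X <- matrix(acc, nrow = npos, ncol = M)

  if (cfg$orientation_normalized) {
    cellsq <- ncs^2L
    bintot <- matrix(0, npos, nb)
    for (b in seq_len(nb)) {
      bintot[, b] <- rowSums(X[, b + nb * (0:(cellsq - 1L)), drop = FALSE])
    }
    mx <- bintot[, 1L]
    for (b in 2:nb) mx <- pmax(mx, bintot[, b])
    thr <- mx - (1e-9 * mx + 1e-12)
    dom <- rep(0L, npos)
    for (b in nb:1) dom[bintot[, b] >= thr] <- b - 1L
    for (m in sort(unique(dom))) {
      if (m == 0L) next
      sel <- dom == m
      shifted <- (seq_len(nb) - 1L + m) %% nb
      take <- rep((0:(cellsq - 1L)) * nb, each = nb) + rep(shifted + 1L, cellsq)
      X[sel, ] <- X[sel, take, drop = FALSE]
    }
  }

  if (cfg$normalization != "none") {
    eps <- 1e-12
    rn <- sqrt(rowSums(X * X))
    nz <- rn > eps
    X[nz, ] <- X[nz, , drop = FALSE] / rn[nz]
    if (cfg$normalization == "l2_clip") {
      X[X > cfg$clip_threshold] <- cfg$clip_threshold
      rn2 <- sqrt(rowSums(X * X))
      nz2 <- rn2 > eps
      X[nz2, ] <- X[nz2, , drop = FALSE] / rn2[nz2]
      X[!nz2, ] <- 0
    }
    X[!nz, ] <- 0
  }

  out <- array(X, dim = c(hh, ww, M))
  attr(out, "source_shape") <- c(h, w)
  attr(out, "config") <- cfg
  class(out) <- c("sift_image", class(out))
  out
}

#' Channel permutation induced by a quarter-turn rotation
#'
#' Rotating the source image 90 degrees counter-clockwise rotates each
#' descriptor window: the cell grid turns by a quarter turn and every
#' gradient orientation shifts by 90 degrees, i.e. by `bins/4` histogram
#' bins. The returned permutation `P` (1-based) satisfies
#' `desc_rotated == desc_original[P]` for interior pixels (see
#' [sift_rot90_residual()] for the exact spatial alignment).
#'
#' @param cfg a [dense_sift_config()]; `orientation_bins` must be divisible
#'   by 4 and `orientation_normalized` must be off for the equivariance to
#'   hold.
#' @return integer permutation of `1:M`.
#' @export
rot90_channel_permutation <- function(cfg = dense_sift_config()) {
  if (cfg$orientation_bins %% 4L != 0L) {
    stop("unsupported configuration: orientation_bins must be divisible by 4")
  }
  M <- cfg$descriptor_dim
  ncs <- cfg$cells_per_side
  nb <- cfg$orientation_bins
  lay <- channel_layout(0:(M - 1L), cfg)
  # descriptor of rotated image, channel (r', c', b') = original channel
  # (c', ncs-1-r', (b' + nb/4) mod nb)
  src <- channel_index(lay$cell_col, ncs - 1L - lay$cell_row,
                       (lay$bin + nb %/% 4L) %% nb, cfg)
  as.integer(src + 1L)
}

#' Channel permutation induced by a horizontal flip
#'
#' Mirroring the source image left-right mirrors the cell columns and
#' reflects gradient orientations (`theta -> pi - theta`), i.e. bin
#' `b -> (bins/2 - b) mod bins`.
#'
#' @param cfg a [dense_sift_config()].
#' @return integer permutation of `1:M`.
#' @export
flip_channel_permutation <- function(cfg = dense_sift_config()) {
  M <- cfg$descriptor_dim
  ncs <- cfg$cells_per_side
  nb <- cfg$orientation_bins
  lay <- channel_layout(0:(M - 1L), cfg)
  src <- channel_index(lay$cell_row, ncs - 1L - lay$cell_col,
                       (nb %/% 2L - lay$bin) %% nb, cfg)
  as.integer(src + 1L)
}

#' Quarter-turn equivariance residual of the SIFT image
#'
#' Computes `max |S(rot90(I))[i, j, ] - S(I)[j, W - i + 2, P]|` over an
#' interior region. Because the even-sized descriptor window is centered on
#' the half-pixel `(r - 0.5, c - 0.5)`, the descriptor grid of the rotated
#' image aligns with the original grid at column `W - i + 2` (one pixel off
#' a plain spatial quarter-turn); on that alignment the equivariance is
#' exact away from boundaries.
#'
#' @param img gray image matrix (interior must be larger than 2 * margin).
#' @param cfg a [dense_sift_config()] with stride 1.
#' @param margin boundary margin in pixels excluded from the comparison
#'   (default 8, covering window + gradient reach).
#' @return maximum absolute elementwise residual over the interior.
#' @export
sift_rot90_residual <- function(img, cfg = dense_sift_config(), margin = 8L) {
  stopifnot(cfg$stride == 1L)
  img <- as_gray_image(img)
  h <- nrow(img); w <- ncol(img)
  S <- compute_sift_image(img, cfg)
  R <- compute_sift_image(rot90_image(img), cfg)   # dims w x h x M
  P <- rot90_channel_permutation(cfg)
  is <- seq.int(margin + 1L, w - margin)           # rows of R
  js <- seq.int(margin + 1L, h - margin)           # cols of R
  # R[i, j, ] should equal S[j, w - i + 2, P]
  pred <- S[js, w - is + 2L, P, drop = FALSE]          # dims |js| x |is| x M
  pred <- aperm(pred, c(2L, 1L, 3L))
  max(abs(R[is, js, , drop = FALSE] - pred))
}

#' Horizontal-flip equivariance residual of the SIFT image
#'
#' Computes `max |S(flip(I))[i, j, ] - S(I)[i, W - j + 2, P_flip]|` over an
#' interior region; the one-pixel alignment is as in
#' [sift_rot90_residual()].
#'
#' @inheritParams sift_rot90_residual
#' @return maximum absolute elementwise residual over the interior.
#' @export
sift_flip_residual <- function(img, cfg = dense_sift_config(), margin = 8L) {
  stopifnot(cfg$stride == 1L)
  img <- as_gray_image(img)
  h <- nrow(img); w <- ncol(img)
  S <- compute_sift_image(img, cfg)
  G <- compute_sift_image(flip_image(img), cfg)
  P <- flip_channel_permutation(cfg)
  is <- seq.int(margin + 1L, h - margin)
  js <- seq.int(margin + 1L, w - margin)
  pred <- S[is, w - js + 2L, P, drop = FALSE]
  max(abs(G[is, js, , drop = FALSE] - pred))
}

#' Dominant scale from detector scale samples
#'
#' The dense descriptor uses one fixed neighborhood size; it is chosen as
#' the arithmetic mean of the scale estimates produced by a keypoint
#' detector run over training images (the detector itself is external).
#'
#' @param scales numeric vector of positive finite scale samples.
#' @return the mean scale.
#' @export
estimate_dominant_scale <- function(scales) {
  if (length(scales) == 0L) stop("empty input: no scale samples")
  if (!all(is.finite(scales)) || any(scales <= 0)) {
    stop("scale samples must be positive and finite")
  }
  mean(scales)
}
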