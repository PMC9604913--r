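#' Synthetic oriented-texture dataset specification
#'
#' Describes a deterministic generator of textured single-channel images
#' whose class identity is carried by local gradient-orientation statistics:
#' each image is a grid of sinusoidal-grating patches, each patch oriented
#' at the class's dominant orientation plus an independent random local
#' rotation. This emulates the regime in which sub-regions of an image can
#' rotate independently without changing the image's class.
#'
#' @param num_classes number of classes (>= 2). Default class orientations
#'   are evenly spaced over `[0, pi)` (classes 0 and `pi/2` for two
#'   classes).
#' @param images_per_class images generated per class.
#' @param image_size square image side in pixels (>= 16).
#' @param patch_grid patches per side (default 4, i.e. 16-pixel patches at
#'   the default size — large enough for the 8-pixel descriptor window).
#' @param class_orientations optional numeric vector of per-class dominant
#'   orientations in radians.
#' @param local_rotation maximum random rotation (radians) applied
#'   independently per patch, uniform on `[-local_rotation,
#'   local_rotation]`. At `pi` the local orientation is fully randomized and
#'   class information is destroyed.
#' @param cycles_per_patch spatial frequency of the gratings (cycles across
#'   one patch).
#' @param noise_sigma additive Gaussian intensity noise (images are clipped
#'   to `[0, 1]`).
#' @param seed integer seed; orientations, phases and noise all flow from
#'   it.
#' @return object of class `synthetic_texture_spec`.
#' @export
synthetic_texture_spec <- function(num_classes = 2L,
                                   images_per_class = 20L,
                                   image_size = 64L,
                                   patch_grid = 4L,
                                   class_orientations = NULL,
                                   local_rotation = pi / 6,
                                   cycles_per_patch = 4,
                                   noise_sigma = 0.05,
                                   seed = 0L) {
  spec <- list(num_classes = as.integer(num_classes),
               images_per_class = as.integer(images_per_class),
               image_size = as.integer(image_size),
               patch_grid = as.integer(patch_grid),
               class_orientations = class_orientations %||%
                 (seq_len(num_classes) - 1L) * pi / num_classes,
               local_rotation = as.numeric(local_rotation),
               cycles_per_patch = as.numeric(cycles_per_patch),
               noise_sigma = as.numeric(noise_sigma),
               seed = as.integer(seed))
  if (spec$num_classes < 2L) stop("validation error: num_classes must be >= 2")
  if (spec$image_size < 16L) stop("validation error: image_size must be >= 16")
  if (spec$images_per_class < 1L) {
    stop("validation error: images_per_class must be >= 1")
  }
  if (spec$patch_grid < 1L || spec$image_size %% spec$patch_grid != 0L) {
    stop("validation error: patch_grid must divide image_size")
  }
  if (length(spec$class_orientations) != spec$num_classes) {
    stop("validation error: need one orientation per class")
  }
  if (spec$noise_sigma < 0) stop("validation error: noise_sigma must be >= 0")
  if (spec$local_rotation < 0) {
    stop("validation error: local_rotation must be >= 0")
  }
  class(spec) <- "synthetic_texture_spec"
  spec
}

# One grating patch: 0.5 + 0.4 * sin(2*pi*f*(x cos + y sin) + phase).
grating_patch <- function(side, theta, cycles, phase) {
  xy <- seq_len(side) - (side + 1) / 2
  proj <- outer(xy, xy, function(y, x) x * cos(theta) + y * sin(theta))
  0.5 + 0.4 * sin(2 * pi * cycles * proj / side + phase)
}

#' Generate a synthetic oriented-texture dataset
#'
#' A pure function of the spec (including its seed): two calls with the same
#' spec produce bitwise-identical datasets. Classes are balanced.
#'
#' @param spec a [synthetic_texture_spec()].
#' @param split `"train"` or `"test"` (metadata only).
#' @return object of class `labeled_dataset`: list with `images` (list of
#'   matrices), `labels` (0-based integers), `class_names`, `split`.
#' @export
gen_texture_dataset <- function(spec, split = c("train", "test")) {
  split <- match.arg(split)
  side <- spec$image_size %/% spec$patch_grid
  n <- spec$num_classes * spec$images_per_class
  images <- vector("list", n)
  labels <- integer(n)
  withr::with_seed(spec$seed, {
    i <- 0L
    for (cl in seq_len(spec$num_classes) - 1L) {
      for (im in seq_len(spec$images_per_class)) {
        i <- i + 1L
        img <- matrix(0, spec$image_size, spec$image_size)
        for (pr in seq_len(spec$patch_grid) - 1L) {
          for (pc in seq_len(spec$patch_grid) - 1L) {
            theta <- spec$class_orientations[cl + 1L] +
              stats::runif(1, -spec$local_rotation, spec$local_rotation)
            phase <- stats::runif(1, 0, 2 * pi)
            img[pr * side + seq_len(side), pc * side + seq_len(side)] <-
              grating_patch(side, theta, spec$cycles_per_patch, phase)
          }
        }
        if (spec$noise_sigma > 0) {
          img <- img + matrix(stats::rnorm(length(img), 0, spec$noise_sigma),
                              nrow(img))
        }
        images[[i]] <- pmin(pmax(img, 0), 1)
        labels[i] <- cl
      }
    }
  })
  structure(list(images = images, labels = labels,
                 class_names = sprintf("class%02d", seq_len(spec$num_classes) - 1L),
                 split = split),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("labeled_dataset (%s): %d images, %d classes\n",
              x$split, length(x$images), length(x$class_names)))
  invisible(x)
}

#' Analytic fixture images
#'
#' A fixed registry of small images with known descriptor behavior:
#' `constant` (all 0.5, zero descriptors), `ramp_x` / `ramp_y` (linear
#' ramps, interior gradient orientation 0 / pi/2), `step_edge` (9x9
#' vertical step), `checkerboard`, and five seeded pseudorandom images
#' (`rand_1` ... `rand_5`, 8x8 up to 32x32). Names and contents are stable
#' across calls.
#'
#' @return named list of gray-image matrices, each at most 32 x 32.
#' @export
analytic_fixtures <- function() {
  fx <- list(
    constant = matrix(0.5, 16L, 16L),
    ramp_x = matrix(rep(seq(0, 1, length.out = 16L), each = 16L), 16L, 16L),
    ramp_y = matrix(rep(seq(0, 1, length.out = 16L), times = 16L), 16L, 16L),
    step_edge = cbind(matrix(0, 9L, 4L), matrix(0, 9L, 1L) + 0.5,
                      matrix(1, 9L, 4L)),
    checkerboard = outer(1:16, 1:16,
                         function(r, c) ((r %/% 4L + c %/% 4L) %% 2L) * 1)
  )
  sizes <- c(8L, 16L, 24L, 32L, 20L)
  for (k in 1:5) {
    fx[[paste0("rand_", k)]] <- withr::with_seed(k, {
      matrix(stats::runif(sizes[k]^2), sizes[k], sizes[k])
    })
  }
  fx
}
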