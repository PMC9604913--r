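test_that("config validates descriptor geometry", {
  cfg <- dense_sift_config()
  expect_equal(cfg$descriptor_dim, 128L)
  expect_equal(cfg$patch_size, 8L)
  expect_error(dense_sift_config(patch_size = 7), "multiple")
  expect_error(dense_sift_config(stride = 0), "stride")
  expect_error(dense_sift_config(clip_threshold = 0), "clip_threshold")
})

test_that("gradients: constant image, ramps, and a finite-difference loop", {
  g <- image_gradients(matrix(0.5, 12, 12))
  expect_true(all(g$magnitude == 0))
  expect_true(all(g$orientation == 0))

  # horizontal ramp: interior magnitude constant, orientation 0
  w <- 16
  ramp <- matrix(rep((seq_len(w) - 1) / w, each = w), w, w)
  g <- image_gradients(ramp)
  inner <- 2:(w - 1)
  expect_equal(max(abs(g$magnitude[inner, inner] - 1 / w)), 0, tolerance = 1e-12)
  expect_true(all(g$orientation[inner, inner] == 0))

  # pseudorandom 8x8 vs an independent per-pixel finite-difference loop
  img <- withr::with_seed(0, matrix(runif(64), 8, 8))
  g <- image_gradients(img, "reflect")
  ref <- function(i, n) min(max(i, 1L), n) # not used: reflect is symmetric
  sym <- function(i, n) if (i < 1L) 1L - i + 0L else if (i > n) 2L * n + 1L - i else i
  for (r in 1:8) for (c in 1:8) {
    dx <- (img[r, sym(c + 1L, 8L)] - img[r, sym(c - 1L, 8L)]) / 2
    dy <- (img[sym(r + 1L, 8L), c] - img[sym(r - 1L, 8L), c]) / 2
    expect_equal(g$dx[r, c], dx, tolerance = 1e-12)
    expect_equal(g$dy[r, c], dy, tolerance = 1e-12)
    expect_equal(g$magnitude[r, c], sqrt(dx^2 + dy^2), tolerance = 1e-12)
    expect_equal(g$orientation[r, c],
                 if (dx == 0 && dy == 0) 0 else atan2(dy, dx) %% (2 * pi),
                 tolerance = 1e-12)
  }

  expect_error(image_gradients(matrix(0.1, 2, 2), "reflect"), "degenerate")
})

test_that("reference descriptor: zeros on constant input, M = 128 entries", {
  img <- matrix(0.25, 16, 16)
  d <- descriptor_at(img, 8, 8)
  expect_length(d, 128L)
  expect_true(all(d == 0))
  img2 <- withr::with_seed(3, matrix(runif(144), 12, 12))
  expect_length(descriptor_at(img2, 1, 1), 128L)
  expect_length(descriptor_at(img2, 12, 12), 128L)
})

test_that("step-edge descriptor matches an independent nested-loop sum", {
  # 9x9 vertical step edge; hand-rolled accumulation written against the
  # documented conventions, independent of the package code paths.
  img <- analytic_fixtures()$step_edge
  cfg <- dense_sift_config()
  # gradients of the reflect-padded image, via direct central differences
  p <- 5L
  sym <- function(i, n) {   # half-sample symmetric reflection, 1-based
    j <- (i - 1L) %% (2L * n); if (j >= n) 2L * n - 1L - j else j
  }
  at <- function(r, c) img[sym(r, 9L) + 1L, sym(c, 9L) + 1L]
  ref <- numeric(128)
  for (dy in -4:3) for (dx in -4:3) {
    r <- 5L + dy; c <- 5L + dx
    gx <- (at(r, c + 1L) - at(r, c - 1L)) / 2
    gy <- (at(r + 1L, c) - at(r - 1L, c)) / 2
    m <- sqrt(gx^2 + gy^2)
    if (m == 0) next
    th <- atan2(gy, gx) %% (2 * pi)
    t <- th * 8 / (2 * pi)
    ur <- (dy + 4.5) / 2 - 0.5; uc <- (dx + 4.5) / 2 - 0.5
    i0 <- floor(ur); fr <- ur - i0
    j0 <- floor(uc); fc <- uc - j0
    b0 <- floor(t) %% 8; fb <- t - floor(t)
    for (a in 0:1) for (b in 0:1) for (bb in 0:1) {
      ci <- i0 + a; cj <- j0 + b
      if (ci < 0 || ci > 3 || cj < 0 || cj > 3) next
      w <- (if (a == 0) 1 - fr else fr) * (if (b == 0) 1 - fc else fc) *
        (if (bb == 0) 1 - fb else fb)
      bin <- (b0 + bb) %% 8
      k <- (ci * 4 + cj) * 8 + bin + 1
      ref[k] <- ref[k] + m * w
    }
  }
  n <- sqrt(sum(ref^2)); ref <- ref / n
  ref <- pmin(ref, 0.2); ref <- ref / sqrt(sum(ref^2))
  expect_equal(descriptor_at(img, 5, 5, cfg), ref, tolerance = 1e-10)
})

test_that("SIFT image: shape, constant-zero, and per-pixel loop agreement", {
  cfg <- dense_sift_config()
  S0 <- compute_sift_image(matrix(0.7, 16, 16), cfg)
  expect_equal(dim(S0), c(16L, 16L, 128L))
  expect_true(all(S0 == 0))

  img <- withr::with_seed(0, matrix(runif(32 * 32), 32, 32))
  expect_equal(dim(compute_sift_image(img, cfg)), c(32L, 32L, 128L))

  img24 <- withr::with_seed(1, matrix(runif(24 * 24), 24, 24))
  expect_lt(sift_loop_gap(img24, cfg), 1e-10)
})

test_that("hard binning and orientation normalization agree with the loop", {
  img <- withr::with_seed(4, matrix(runif(18 * 18), 18, 18))
  expect_lt(sift_loop_gap(img, dense_sift_config(soft_binning = FALSE)), 1e-10)
  expect_lt(sift_loop_gap(img, dense_sift_config(orientation_normalized = TRUE)),
            1e-10)
  expect_lt(sift_loop_gap(img, dense_sift_config(boundary_mode = "zero",
                                                 normalization = "l2")), 1e-10)
})

test_that("descriptors are nonnegative with norm at most one; photometric invariance", {
  img <- withr::with_seed(5, matrix(runif(28 * 28), 28, 28))
  S <- compute_sift_image(img)
  X <- matrix(S, ncol = 128)
  expect_true(all(X >= 0))
  expect_true(all(sqrt(rowSums(X^2)) <= 1 + 1e-8))
  for (a in c(0.5, 2)) {
    for (b in c(-0.1, 0.2)) {
      expect_lt(max(abs(compute_sift_image(a * img + b) - S)), 1e-8)
    }
  }
})

test_that("stride subsamples the stride-1 SIFT image exactly", {
  img <- withr::with_seed(6, matrix(runif(21 * 27), 21, 27))
  S1 <- compute_sift_image(img, dense_sift_config(stride = 1))
  for (s in c(2L, 3L)) {
    Ss <- compute_sift_image(img, dense_sift_config(stride = s))
    expect_equal(dim(Ss), c(as.integer(ceiling(21 / s)),
                            as.integer(ceiling(27 / s)), 128L))
    expect_identical(unclass(Ss)[, , ],
                     unclass(S1)[seq(1, 21, s), seq(1, 27, s), ])
  }
})

test_that("dominant scale is the mean of detector scale samples", {
  expect_equal(estimate_dominant_scale(c(8, 8, 8)), 8)
  expect_equal(estimate_dominant_scale(c(2, 4, 6, 8)), 5)
  x <- withr::with_seed(0, rgamma(1000, shape = 16, rate = 2))  # mean 8
  se <- sd(x) / sqrt(length(x))
  expect_lt(abs(estimate_dominant_scale(x) - 8), 3 * se)
  expect_error(estimate_dominant_scale(numeric(0)), "empty")
  expect_error(estimate_dominant_scale(c(1, -2)), "positive")
})
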