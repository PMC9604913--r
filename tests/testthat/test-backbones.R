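test_that("backbones produce fixed-length features regardless of input channels", {
  rn128 <- build_backbone(128L, 7L, "resnet18", seed = 0)
  x <- withr::with_seed(0, array(runif(32 * 32 * 128) / 10, c(32, 32, 128, 1)))
  f <- extract_features(rn128, x)
  expect_equal(dim(f), c(1L, 512L))
  expect_true(all(is.finite(f)))

  rn1 <- build_backbone(1L, 7L, "resnet18", seed = 0)
  x1 <- withr::with_seed(1, array(runif(64 * 64), c(64, 64, 1, 1)))
  expect_equal(dim(extract_features(rn1, x1)), c(1L, 512L))

  # identical weights + eval mode => identical outputs
  expect_identical(extract_features(rn1, x1), extract_features(rn1, x1))

  # spatial size below the topology minimum is a configuration error
  small <- withr::with_seed(2, array(runif(16 * 16), c(16, 16, 1, 1)))
  expect_error(siftcnn:::model_forward(rn1, small), "configuration error")
  expect_error(siftcnn:::model_forward(rn1, x), "channels")
})

test_that("reduction stem follows convolution output-size arithmetic", {
  stem <- build_reduction_stem(seed = 0)
  x88 <- withr::with_seed(0, array(runif(88 * 88 * 128) / 20, c(88, 88, 128, 1)))
  y <- reduction_stem(x88, stem)
  expect_equal(dim(y), c(22L, 22L, 64L, 1L))

  x44 <- x88[1:44, 1:44, , , drop = FALSE]
  expect_equal(dim(reduction_stem(x44, stem)), c(11L, 11L, 64L, 1L))

  # property: floor arithmetic of the three convolutions over many sizes
  for (s in c(32L, 40L, 57L, 64L, 100L, 128L)) {
    xs <- array(0, c(s, s, 128L, 1L))
    out <- dim(reduction_stem(xs, stem))[1L]
    s1 <- (s + 2L - 3L) %/% 2L + 1L
    s2 <- (s1 + 2L - 3L) %/% 2L + 1L
    expect_equal(out, s2)   # third conv is stride 1, size-preserving
  }

  # zero input stays zero through zero-bias convs and fresh BN (eval mode)
  expect_true(all(reduction_stem(array(0, c(32, 32, 128, 1)), stem) == 0))

  expect_error(reduction_stem(array(0, c(32, 32, 64, 1)), stem), "shape error")
})

test_that("late fusion concatenates (pixel, sift) to 1024 and is an affine map", {
  head <- build_fusion_head(512L, 7L, seed = 0)
  expect_equal(head$fused_dim, 1024L)
  W <- head$linear$params$W
  expect_equal(dim(W), c(7L, 1024L))
  b <- head$linear$params$b

  p <- withr::with_seed(0, rnorm(512))
  s <- withr::with_seed(1, rnorm(512))
  sc <- late_fusion_forward(p, s, head)
  A <- W[, 1:512]; B <- W[, 513:1024]
  expect_equal(sc, drop(A %*% p + B %*% s + b), tolerance = 1e-6)

  expect_equal(late_fusion_forward(numeric(512), numeric(512), head), b)
  expect_error(late_fusion_forward(p[1:256], s, head), "shape error")
})

test_that("SVM selection reproduces an exhaustive CV grid search", {
  set.seed(0)
  n <- 20
  feats <- rbind(matrix(rnorm(n * 2, -2), n, 2), matrix(rnorm(n * 2, 2), n, 2))
  labs <- rep(0:1, each = n)
  spec <- svm_spec(cost_grid = c(0.01, 1, 100))
  fit <- fit_svm_on_features(feats, labs, spec, seed = 0)
  expect_equal(mean(predict(fit, feats) == factor(labs)), 1.0)

  # independent exhaustive CV over the same folds
  folds <- siftcnn:::stratified_folds(labs + 1L, 5L, seed = 0)
  accs <- sapply(spec$cost_grid, function(cost) {
    mean(sapply(1:5, function(f) {
      m <- e1071::svm(feats[folds != f, ], factor(labs[folds != f]),
                      kernel = "linear", cost = cost, scale = FALSE)
      mean(predict(m, feats[folds == f, ]) == factor(labs[folds == f]))
    }))
  })
  best <- spec$cost_grid[which(accs >= max(accs) - 1e-12)[1]]
  expect_equal(fit$best_cost, best)
  expect_equal(fit$cv_table$cv_accuracy, unname(accs))

  # grid-order invariance (ties break toward the smallest cost)
  fit2 <- fit_svm_on_features(feats, labs,
                              svm_spec(cost_grid = c(100, 0.01, 1)), seed = 0)
  expect_equal(fit2$best_cost, fit$best_cost)
})

test_that("SVM on permuted labels stays in the permutation-null band", {
  withr::with_seed(1, {
    feats <- matrix(rnorm(60 * 4), 60, 4)
    labs <- sample(rep(0:1, each = 30))
  })
  fit <- fit_svm_on_features(feats, labs, svm_spec(cost_grid = 1), seed = 1)
  expect_gte(max(fit$cv_table$cv_accuracy), 0.25)
  expect_lte(max(fit$cv_table$cv_accuracy), 0.75)
})

test_that("SVM errors when a class has fewer samples than folds", {
  feats <- matrix(rnorm(14), 7, 2)
  expect_error(fit_svm_on_features(feats, c(0, 0, 0, 0, 0, 1, 1), svm_spec()),
               "stratification error")
})

test_that("temporal aggregation defaults to mean pooling", {
  v <- withr::with_seed(0, rnorm(512))
  expect_equal(temporal_aggregate(list(v)), v)
  expect_equal(temporal_aggregate(list(v, -v)), numeric(512))
  M <- withr::with_seed(0, matrix(rnorm(29 * 512), 29, 512))
  ref <- numeric(512)
  for (t in 1:29) ref <- ref + M[t, ]
  expect_equal(temporal_aggregate(M), ref / 29, tolerance = 1e-12)
  expect_error(temporal_aggregate(list()), "empty")
})

test_that("gradients reach the first layer of the SIFT backbone and the stem", {
  cfg <- train_config(initial_lr = 0.01, epochs = 1L, batch_size = 4L, seed = 0)
  x <- withr::with_seed(0, array(runif(16 * 16 * 128) / 5, c(16, 16, 128, 4)))
  y <- c(0L, 1L, 0L, 1L)

  m <- build_backbone(128L, 2L, "tiny", seed = 0)
  fit <- train_classifier(m, x, y, cfg)
  expect_gt(max(abs(fit$model$features[[1]]$params$W - m$features[[1]]$params$W)), 0)

  sq <- build_sequence_backbone(2L, "tiny", seed = 0)
  xs <- withr::with_seed(1, array(runif(32 * 32 * 128 * 4) / 5, c(32, 32, 128, 4)))
  fit2 <- train_classifier(sq, xs, y, cfg)
  expect_gt(max(abs(fit2$model$features[[1]]$params$W - sq$features[[1]]$params$W)), 0)
})

test_that("fusion model trains end-to-end and matches the affine head oracle", {
  px <- build_backbone(1L, 2L, "tiny", seed = 0)
  sx <- build_backbone(128L, 2L, "tiny", seed = 1)
  fm <- build_fusion_model(px, sx, 2L, seed = 2)
  xp <- withr::with_seed(0, array(runif(16 * 16 * 4), c(16, 16, 1, 4)))
  xs <- withr::with_seed(1, array(runif(16 * 16 * 128 * 4) / 5, c(16, 16, 128, 4)))
  y <- c(0L, 1L, 1L, 0L)

  fw <- siftcnn:::fusion_forward(fm, list(pixel = xp, sift = xs))
  fp <- t(extract_features(px, xp))
  fs <- t(extract_features(sx, xs))
  expect_equal(fw$scores, late_fusion_forward(fp, fs, fm$head), tolerance = 1e-10)

  cfg <- train_config(initial_lr = 0.01, epochs = 1L, batch_size = 4L, seed = 0)
  fit <- train_classifier(fm, list(pixel = xp, sift = xs), y, cfg)
  expect_gt(max(abs(fit$model$pixel$features[[1]]$params$W -
                      fm$pixel$features[[1]]$params$W)), 0)
  expect_gt(max(abs(fit$model$sift$features[[1]]$params$W -
                      fm$sift$features[[1]]$params$W)), 0)
  expect_length(predict_labels(fit$model, list(pixel = xp, sift = xs)), 4L)
})
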