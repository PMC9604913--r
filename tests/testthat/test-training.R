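test_that("step schedule divides the learning rate by 10 every 30 epochs", {
  cfg <- train_config(initial_lr = 0.1)
  expect_equal(lr_at_epoch(cfg, 0), 0.1)
  expect_equal(lr_at_epoch(cfg, 29), 0.1)
  expect_equal(lr_at_epoch(cfg, 30), 0.01)
  expect_equal(lr_at_epoch(cfg, 60), 0.001)
  expect_equal(lr_at_epoch(cfg, 90), 0.0001)
  cloud <- train_config(initial_lr = 0.001, weight_decay = 2e-4)
  expect_equal(lr_at_epoch(cloud, 45), 1e-4)
  expect_error(lr_at_epoch(cfg, -1), "range error")

  # non-increasing step function with exactly ceil(epochs/30) - 1 drops
  lrs <- sapply(0:99, function(e) lr_at_epoch(cfg, e))
  expect_true(all(diff(lrs) <= 0))
  expect_equal(sum(diff(lrs) < 0), ceiling(100 / 30) - 1)
})

make_toy <- function(n_per_class = 5, size = 16) {
  imgs <- c(lapply(seq_len(n_per_class),
                   function(i) withr::with_seed(i, matrix(runif(size^2, 0, 0.3), size))),
            lapply(seq_len(n_per_class),
                   function(i) withr::with_seed(100 + i, matrix(runif(size^2, 0.7, 1), size))))
  list(x = imgs, y = rep(0:1, each = n_per_class))
}

test_that("a small backbone overfits a separable toy set", {
  toy <- make_toy()
  cfg <- train_config(initial_lr = 0.05, epochs = 30L, batch_size = 5L, seed = 1)
  fit <- train_classifier(build_backbone(1L, 2L, "tiny", seed = 0),
                          toy$x, toy$y, cfg)
  expect_equal(nrow(fit$history), 30L)
  expect_equal(tail(fit$history$accuracy, 1), 1.0)
  expect_equal(evaluate(fit$model, toy$x, toy$y)$accuracy, 1.0)
})

test_that("zero-epoch training is a no-op and equal seeds reproduce the loss", {
  toy <- make_toy(3)
  m <- build_backbone(1L, 2L, "tiny", seed = 0)
  fit0 <- train_classifier(m, toy$x, toy$y, train_config(epochs = 0L))
  expect_identical(siftcnn:::collect_params(fit0$model$features),
                   siftcnn:::collect_params(m$features))
  expect_equal(nrow(fit0$history), 0L)

  cfg <- train_config(initial_lr = 0.02, epochs = 3L, batch_size = 3L, seed = 7)
  f1 <- train_classifier(m, toy$x, toy$y, cfg)
  f2 <- train_classifier(m, toy$x, toy$y, cfg)
  expect_equal(tail(f1$history$loss, 1), tail(f2$history$loss, 1),
               tolerance = 1e-6)
})

test_that("transfer learning copies weights and reinitializes the head as needed", {
  toy <- make_toy(3)
  src <- train_classifier(build_backbone(1L, 2L, "tiny", seed = 0), toy$x, toy$y,
                          train_config(initial_lr = 0.05, epochs = 2L,
                                       batch_size = 3L, seed = 0))$model

  # same class count, zero further epochs: bitwise-equal model incl. head
  tr <- transfer_learn(src, toy$x, toy$y, num_classes = 2L,
                       cfg = train_config(epochs = 0L))
  expect_identical(siftcnn:::collect_params(tr$model$features),
                   siftcnn:::collect_params(src$features))
  expect_identical(tr$model$head$params, src$head$params)

  # different class count: fresh head of the right shape, identical backbone
  tr3 <- transfer_learn(src, toy$x, c(0L, 0L, 0L, 1L, 2L, 2L), num_classes = 3L,
                        cfg = train_config(epochs = 0L))
  expect_identical(siftcnn:::collect_params(tr3$model$features),
                   siftcnn:::collect_params(src$features))
  expect_equal(dim(tr3$model$head$params$W), c(3L, src$feature_dim))
  expect_false(isTRUE(all.equal(tr3$model$head$params$W[1:2, ],
                                src$head$params$W)))

  # channel-count mismatch is an incompatibility error
  xs <- list(withr::with_seed(0, array(runif(16 * 16 * 128), c(16, 16, 128))))
  expect_error(transfer_learn(src, xs, 0L, num_classes = 2L,
                              cfg = train_config(epochs = 0L)),
               "incompatibility")
})

test_that("evaluation: oracle, constant and random predictors", {
  y <- rep(0:3, each = 25)
  oracle <- local({ truth <- y; function(x) truth })
  ev <- evaluate(oracle, x = NULL, y = y, num_classes = 4L)
  expect_equal(ev$accuracy, 1.0)
  expect_true(all(ev$confusion[upper.tri(ev$confusion)] == 0))
  expect_true(all(ev$confusion[lower.tri(ev$confusion)] == 0))
  expect_equal(unname(diag(ev$confusion)), rep(25L, 4))
  expect_equal(unname(rowSums(ev$confusion)), unname(table(y))[1:4],
               ignore_attr = TRUE)

  ev2 <- evaluate(function(x) rep(2L, length(y)), x = NULL, y = y,
                  num_classes = 4L)
  expect_equal(ev2$accuracy, 0.25)

  y7 <- rep(0:6, length.out = 1001)[1:1000]
  pred <- withr::with_seed(0, sample(0:6, 1000, replace = TRUE))
  acc <- evaluate(function(x) pred, x = NULL, y = y7, num_classes = 7L)$accuracy
  band <- binom_band(1 / 7, 1000)
  expect_gt(acc, band[1]); expect_lt(acc, band[2])
})

test_that("augmentation: crops, identity, and flip involution", {
  img <- withr::with_seed(0, matrix(runif(280 * 280), 280, 280))
  out <- augment(img, list(crop_size = 256L, hflip = TRUE), seed = 3)
  expect_equal(dim(out), c(256L, 256L))
  expect_identical(augment(img, list(), seed = 1), img)
  expect_identical(flip_image(flip_image(img)), img)
  expect_identical(augment(img, list(crop_size = 256L), seed = 5),
                   augment(img, list(crop_size = 256L), seed = 5))
  expect_error(augment(matrix(0.5, 32, 32), list(crop_size = 64L)), "range error")
})
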