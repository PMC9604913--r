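#' Training configuration
#'
#' The default recipe is SGD for 100 epochs with an initial learning rate of
#' 0.1 divided by 10 every 30 epochs, momentum 0.9 and no weight decay (the
#' single-image classification recipe). The cloud-type recipe uses
#' `initial_lr = 0.001`, `weight_decay = 2e-4`, `momentum = 0.9` with the
#' same step schedule.
#'
#' @param initial_lr initial learning rate (> 0).
#' @param lr_decay_factor multiplicative decay applied at every step.
#' @param lr_step epochs between decays (default 30).
#' @param epochs total training epochs.
#' @param momentum SGD momentum.
#' @param weight_decay L2 penalty on weights.
#' @param batch_size minibatch size.
#' @param augmentations augmentation policy list passed to [augment()]
#'   (applied to training pixel images only; empty = none).
#' @param seed integer seed governing shuffling (and any augmentation).
#' @return object of class `train_config`.
#' @export
train_config <- function(initial_lr = 0.1, lr_decay_factor = 0.1,
                         lr_step = 30L, epochs = 100L, momentum = 0.9,
                         weight_decay = 0, batch_size = 64L,
                         augmentations = list(), seed = 0L) {
  cfg <- list(initial_lr = as.numeric(initial_lr),
              lr_decay_factor = as.numeric(lr_decay_factor),
              lr_step = as.integer(lr_step),
              epochs = as.integer(epochs),
              momentum = as.numeric(momentum),
              weight_decay = as.numeric(weight_decay),
              batch_size = as.integer(batch_size),
              augmentations = augmentations,
              seed = as.integer(seed))
  if (cfg$initial_lr <= 0) stop("initial_lr must be > 0")
  if (cfg$epochs < 0L) stop("epochs must be >= 0")
  if (cfg$batch_size < 1L) stop("batch_size must be >= 1")
  if (cfg$lr_step < 1L) stop("lr_step must be >= 1")
  class(cfg) <- "train_config"
  cfg
}

#' Learning rate at a given epoch
#'
#' Step schedule: `initial_lr * lr_decay_factor ^ floor(epoch / lr_step)`.
#' With the defaults this reproduces 0.1, 0.01, 0.001, 0.0001 at epochs 0,
#' 30, 60, 90.
#'
#' @param cfg a [train_config()].
#' @param epoch 0-based epoch index in `[0, cfg$epochs)`.
#' @return the learning rate.
#' @export
lr_at_epoch <- function(cfg, epoch) {
  if (any(epoch < 0)) stop("range error: epoch must be >= 0")
  if (any(epoch >= cfg$epochs)) stop("range error: epoch beyond cfg$epochs")
  cfg$initial_lr * cfg$lr_decay_factor^(epoch %/% cfg$lr_step)
}

#' Train a classifier by minibatch SGD
#'
#' Minimizes softmax cross-entropy with SGD + momentum under the step
#' learning-rate schedule of `cfg`. Deterministic given `cfg$seed`
#' (shuffling is the only source of randomness; batch norm statistics follow
#' the data order). With `cfg$epochs = 0` the model is returned unchanged
#' with an empty history.
#'
#' @param model a `siftcnn_model` or `siftcnn_fusion`.
#' @param x input tensor `H x W x C x N`, a list of `H x W x C` arrays, or —
#'   for a fusion model — `list(pixel = , sift = )` of such tensors.
#' @param y integer class labels, 0-based, length N.
#' @param cfg a [train_config()].
#' @return list with the trained `model` and a `history` data.frame (epoch,
#'   lr, loss, accuracy), one row per epoch.
#' @export
train_classifier <- function(model, x, y, cfg = train_config()) {
  fusion <- inherits(model, "siftcnn_fusion")
  if (fusion) {
    x <- list(pixel = as_input_tensor(x$pixel), sift = as_input_tensor(x$sift))
    n <- dim(x$pixel)[4L]
    stopifnot(dim(x$sift)[4L] == n)
  } else {
    x <- as_input_tensor(x)
    n <- dim(x)[4L]
  }
  y <- as.integer(y)
  stopifnot(length(y) == n, n >= 1L, all(y >= 0L))
  history <- data.frame(epoch = integer(), lr = numeric(),
                        loss = numeric(), accuracy = numeric())
  if (cfg$epochs == 0L) return(list(model = model, history = history))
  state <- new.env(parent = emptyenv())
  for (ep in seq_len(cfg$epochs) - 1L) {
    lr <- lr_at_epoch(cfg, ep)
    ord <- withr::with_seed(cfg$seed + ep, sample.int(n))
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
    ep_loss <- 0; ep_hits <- 0L
    for (ix in batches) {
      xb <- if (fusion) {
        list(pixel = x$pixel[, , , ix, drop = FALSE],
             sift = x$sift[, , , ix, drop = FALSE])
      } else {
        x[, , , ix, drop = FALSE]
      }
      if (fusion) {
        fw <- fusion_forward(model, xb, training = TRUE)
        model <- fw$model
        ls <- softmax_xent(fw$scores, y[ix])
        gr <- fusion_backward(model, fw$caches, ls$dscores)
        model <- fusion_sgd_step(model, gr, state, lr, cfg$momentum,
                                 cfg$weight_decay)
      } else {
        fw <- model_forward(model, xb, training = TRUE)
        model <- fw$model
        ls <- softmax_xent(fw$scores, y[ix])
        gr <- model_backward(model, fw$caches, ls$dscores)
        model <- model_sgd_step(model, gr, state, lr, cfg$momentum,
                                cfg$weight_decay)
      }
      ep_loss <- ep_loss + ls$loss * length(ix)
      pred <- max.col(t(fw$scores), ties.method = "first") - 1L
      ep_hits <- ep_hits + sum(pred == y[ix])
    }
    history <- rbind(history, data.frame(
      epoch = ep, lr = lr, loss = ep_loss / n, accuracy = ep_hits / n))
  }
  list(model = model, history = history)
}

#' Predict class labels
#'
#' Evaluation-mode forward pass (batch norm uses running statistics).
#'
#' @param model a `siftcnn_model` or `siftcnn_fusion`.
#' @param x input tensor(s) as in [train_classifier()].
#' @param batch_size evaluation batch size.
#' @return integer vector of 0-based predicted labels.
#' @export
predict_labels <- function(model, x, batch_size = 16L) {
  fusion <- inherits(model, "siftcnn_fusion")
  if (fusion) {
    x <- list(pixel = as_input_tensor(x$pixel), sift = as_input_tensor(x$sift))
    n <- dim(x$pixel)[4L]
  } else {
    x <- as_input_tensor(x)
    n <- dim(x)[4L]
  }
  pred <- integer(n)
  for (ix in split(seq_len(n), ceiling(seq_len(n) / batch_size))) {
    scores <- if (fusion) {
      fusion_forward(model, list(pixel = x$pixel[, , , ix, drop = FALSE],
                                 sift = x$sift[, , , ix, drop = FALSE]),
                     training = FALSE)$scores
    } else {
      model_forward(model, x[, , , ix, drop = FALSE], training = FALSE)$scores
    }
    pred[ix] <- max.col(t(scores), ties.method = "first") - 1L
  }
  pred
}

#' Evaluate a classifier
#'
#' @param model a trained model (anything accepted by [predict_labels()]),
#'   or a function mapping the input tensor to 0-based labels.
#' @param x inputs as in [train_classifier()].
#' @param y true 0-based labels.
#' @param num_classes number of classes (defaults to `max(y) + 1` or the
#'   model's class count).
#' @return list with `accuracy` and `confusion` (rows = true classes,
#'   columns = predictions).
#' @export
evaluate <- function(model, x, y, num_classes = NULL) {
  y <- as.integer(y)
  if (length(y) == 0L) stop("empty input: no samples to evaluate")
  pred <- if (is.function(model)) as.integer(model(x)) else predict_labels(model, x)
  k <- num_classes %||% (if (is.list(model) && !is.null(model$num_classes))
    model$num_classes else max(y, pred) + 1L)
  confusion <- matrix(0L, k, k,
                      dimnames = list(true = 0:(k - 1L), pred = 0:(k - 1L)))
  for (i in seq_along(y)) {
    confusion[y[i] + 1L, pred[i] + 1L] <- confusion[y[i] + 1L, pred[i] + 1L] + 1L
  }
  list(accuracy = mean(pred == y), confusion = confusion)
}

#' Transfer learning: initialize from a trained source model
#'
#' Copies all backbone weights from the source model. The classification
#' layer is transferred too when the class counts agree and freshly
#' initialized otherwise. All layers remain trainable; with
#' `cfg$epochs = 0` the initialized model is returned without further
#' training (backbone weights bitwise equal to the source).
#'
#' @param source_model a trained `siftcnn_model`.
#' @param x,y target training data as in [train_classifier()].
#' @param num_classes target class count (default `max(y) + 1`).
#' @param cfg a [train_config()] for the further training.
#' @return list with trained `model` and `history` as in
#'   [train_classifier()].
#' @export
transfer_learn <- function(source_model, x, y, num_classes = NULL,
                           cfg = train_config()) {
  y <- as.integer(y)
  num_classes <- as.integer(num_classes %||% (max(y) + 1L))
  xt <- if (is.list(x) && !is.null(x$pixel)) x$pixel else x
  xt <- as_input_tensor(xt)
  if (dim(xt)[3L] != source_model$input_channels) {
    stop("incompatibility error: source model expects ",
         source_model$input_channels, " input channels but target data has ",
         dim(xt)[3L])
  }
  model <- source_model
  if (num_classes != source_model$num_classes) {
    model$head <- withr::with_seed(cfg$seed + 1L,
                                   nn_linear(model$feature_dim, num_classes))
    model$num_classes <- num_classes
  }
  train_classifier(model, x, y, cfg)
}

#' Random crop / horizontal flip augmentation
#'
#' The cloud-task policy: random crops of `crop_size` and horizontal flips
#' with probability 0.5. Offsets are uniform over valid positions;
#' deterministic given `seed`. An empty policy returns the image unchanged.
#'
#' @param img gray image matrix.
#' @param policy list with optional `crop_size` (integer) and `hflip`
#'   (logical).
#' @param seed integer seed.
#' @return augmented image.
#' @export
augment <- function(img, policy = list(), seed = 0L) {
  img <- as_gray_image(img)
  withr::with_seed(as.integer(seed), {
    if (!is.null(policy$crop_size)) {
      cs <- as.integer(policy$crop_size)
      if (cs > nrow(img) || cs > ncol(img)) {
        stop("range error: crop size ", cs, " exceeds image size ",
             nrow(img), "x", ncol(img))
      }
      r0 <- sample.int(nrow(img) - cs + 1L, 1L)
      c0 <- sample.int(ncol(img) - cs + 1L, 1L)
      img <- img[r0:(r0 + cs - 1L), c0:(c0 + cs - 1L), drop = FALSE]
    }
    if (isTRUE(policy$hflip) && stats::runif(1) < 0.5) {
      img <- flip_image(img)
    }
  })
  img
}
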