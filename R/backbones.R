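#' Build a convolutional backbone classifier
#'
#' Constructs a trainable CNN mapping `H x W x input_channels` tensors to a
#' feature vector, followed by a linear classification layer. Two topologies
#' are provided:
#'
#' * `"resnet18"` — an 18-layer residual network (7x7/2 stem convolution,
#'   3x3/2 max pool, four stages of two basic blocks with 64/128/256/512
#'   channels, global average pooling) producing a 512-dimensional feature
#'   vector. This is the reference topology for full-scale experiments; the
#'   SIFT-image variant differs from the pixel variant only in the first
#'   convolution (128 vs 1 input channels).
#' * `"tiny"` — a compact two-stage network (two conv-BN-ReLU stages with
#'   stride 2, global average pooling, 32-dimensional features) for
#'   desk-scale experiments and tests.
#'
#' @param input_channels channels of the input tensor (1 for pixel images,
#'   128 for SIFT images, 64 after the reduction stem).
#' @param num_classes size of the classification layer.
#' @param topology `"resnet18"` or `"tiny"`.
#' @param seed integer seed for weight initialization (He-style normal for
#'   convolutions and linear layers, zero biases).
#' @return object of class `siftcnn_model` with elements `features` (layer
#'   list ending in global average pooling), `head` (linear layer),
#'   `feature_dim`, `input_channels`, `num_classes`, `min_input`.
#' @export
build_backbone <- function(input_channels, num_classes,
                           topology = c("resnet18", "tiny"), seed = 0L) {
  topology <- match.arg(topology)
  stopifnot(input_channels >= 1L, num_classes >= 2L)
  withr::with_seed(as.integer(seed), {
    if (topology == "resnet18") {
      basic_block <- function(cin, cout, stride) {
        main <- list(nn_conv(cin, cout, 3L, stride, 1L), nn_bn(cout),
                     nn_relu(),
                     nn_conv(cout, cout, 3L, 1L, 1L), nn_bn(cout))
        down <- if (stride != 1L || cin != cout) {
          list(nn_conv(cin, cout, 1L, stride, 0L), nn_bn(cout))
        } else NULL
        nn_block(main, down)
      }
      features <- list(
        nn_conv(input_channels, 64L, 7L, 2L, 3L), nn_bn(64L), nn_relu(),
        nn_maxpool(3L, 2L, 1L),
        basic_block(64L, 64L, 1L), basic_block(64L, 64L, 1L),
        basic_block(64L, 128L, 2L), basic_block(128L, 128L, 1L),
        basic_block(128L, 256L, 2L), basic_block(256L, 256L, 1L),
        basic_block(256L, 512L, 2L), basic_block(512L, 512L, 1L),
        nn_gap())
      feature_dim <- 512L
      min_input <- 32L
    } else {
      features <- list(
        nn_conv(input_channels, 16L, 3L, 2L, 1L), nn_bn(16L), nn_relu(),
        nn_conv(16L, 32L, 3L, 2L, 1L), nn_bn(32L), nn_relu(),
        nn_gap())
      feature_dim <- 32L
      min_input <- 8L
    }
    head <- nn_linear(feature_dim, num_classes)
    structure(list(features = features, head = head,
                   input_channels = as.integer(input_channels),
                   num_classes = as.integer(num_classes),
                   feature_dim = feature_dim, topology = topology,
                   min_input = min_input),
              class = "siftcnn_model")
  })
}

#' @export
print.siftcnn_model <- function(x, ...) {
  np <- sum(vapply(collect_params(c(x$features, list(x$head))), length, 1L))
  cat(sprintf("siftcnn_model: %s, %d input channels, %d features, %d classes, %d parameters\n",
              x$topology, x$input_channels, x$feature_dim, x$num_classes, np))
  invisible(x)
}

check_model_input <- function(model, x) {
  d <- dim(x)
  if (length(d) != 4L) stop("input must be an H x W x C x N array")
  if (d[3L] != model$input_channels) {
    stop("shape error: input has ", d[3L], " channels, model expects ",
         model$input_channels)
  }
  if (min(d[1L], d[2L]) < model$min_input) {
    stop("configuration error: spatial size ", d[1L], "x", d[2L],
         " is below the topology minimum of ", model$min_input)
  }
  invisible(TRUE)
}

# Forward through features + head. Returns scores (K x N), features
# (feature_dim x N), caches and the (possibly updated) model.
model_forward <- function(model, x, training = FALSE) {
  check_model_input(model, x)
  f <- seq_forward(model$features, x, training)
  model$features <- f$layers
  h <- layer_forward(model$head, f$y, training)
  list(scores = h$y, feats = f$y,
       caches = list(features = f$caches, head = h$cache), model = model)
}

model_backward <- function(model, caches, dscores) {
  hb <- layer_backward(model$head, caches$head, dscores, need_dx = TRUE)
  fb <- seq_backward(model$features, caches$features, hb$dx, need_dx = FALSE)
  list(features = fb$grads, head = hb$grads)
}

model_sgd_step <- function(model, grads, state, lr, momentum, wd) {
  model$features <- sgd_update_layers(model$features, grads$features, state,
                                      lr, momentum, wd, "f")
  hl <- sgd_update_layers(list(model$head), list(grads$head), state,
                          lr, momentum, wd, "h")
  model$head <- hl[[1L]]
  model
}

#' Extract backbone feature vectors
#'
#' Runs the backbone in evaluation mode (batch-norm uses running statistics)
#' and returns the pooled feature vectors before the classification layer.
#'
#' @param model a `siftcnn_model`.
#' @param x input tensor `H x W x C x N` (or `H x W x C` for one sample).
#' @param batch_size evaluation batch size.
#' @return matrix `N x feature_dim`.
#' @export
extract_features <- function(model, x, batch_size = 16L) {
  x <- as_input_tensor(x)
  n <- dim(x)[4L]
  out <- matrix(NA_real_, n, model$feature_dim)
  for (ix in split(seq_len(n), ceiling(seq_len(n) / batch_size))) {
    f <- seq_forward(model$features, x[, , , ix, drop = FALSE], training = FALSE)
    out[ix, ] <- t(f$y)
  }
  out
}

as_input_tensor <- function(x) {
  if (is.list(x)) {
    d <- dim(x[[1L]])
    if (length(d) == 2L) d <- c(d, 1L)
    arr <- array(NA_real_, c(d, length(x)))
    for (i in seq_along(x)) arr[, , , i] <- x[[i]]
    return(arr)
  }
  d <- dim(x)
  if (length(d) == 2L) {
    dim(x) <- c(d, 1L, 1L)
  } else if (length(d) == 3L) {
    dim(x) <- c(d, 1L)
  }
  x
}

## ---- channel-reduction stem ---------------------------------------------

#' Build the channel-reduction stem for SIFT-image sequences
#'
#' Three convolutions compress a SIFT image before a standard backbone:
#' two 3x3 stride-2 layers mapping 128 to 64 and 64 to 64 channels, then a
#' 3x3 stride-1 layer keeping 64 channels; all padded by 1, each followed by
#' batch normalization and ReLU. An 88 x 88 x 128 SIFT image becomes a
#' 22 x 22 x 64 tensor (spatial downscale by four).
#'
#' @param seed integer seed for weight initialization.
#' @return object of class `siftcnn_stem` (a layer list).
#' @export
build_reduction_stem <- function(seed = 0L) {
  withr::with_seed(as.integer(seed), {
    layers <- list(
      nn_conv(128L, 64L, 3L, 2L, 1L), nn_bn(64L), nn_relu(),
      nn_conv(64L, 64L, 3L, 2L, 1L), nn_bn(64L), nn_relu(),
      nn_conv(64L, 64L, 3L, 1L, 1L), nn_bn(64L), nn_relu())
    structure(list(layers = layers), class = "siftcnn_stem")
  })
}

#' Apply the channel-reduction stem
#'
#' @param x tensor `H x W x 128 x N` (or a single `H x W x 128` array).
#' @param stem a [build_reduction_stem()] object.
#' @param training run batch norm in training mode.
#' @return the reduced tensor, `ceiling(H/4) x ceiling(W/4) x 64 x N`.
#' @export
reduction_stem <- function(x, stem = build_reduction_stem(), training = FALSE) {
  x <- as_input_tensor(x)
  if (dim(x)[3L] != 128L) {
    stop("shape error: the reduction stem expects 128 input channels, got ",
         dim(x)[3L])
  }
  seq_forward(stem$layers, x, training)$y
}

#' Build a sequence backbone (reduction stem + compact CNN)
#'
#' Prepends the channel-reduction stem to a backbone operating on its 64
#' output channels, for per-frame encoding of SIFT-image sequences. The stem
#' and backbone train jointly.
#'
#' @inheritParams build_backbone
#' @return a `siftcnn_model` whose `features` start with the stem layers.
#' @export
build_sequence_backbone <- function(num_classes,
                                    topology = c("resnet18", "tiny"),
                                    seed = 0L) {
  topology <- match.arg(topology)
  stem <- build_reduction_stem(seed = seed + 1L)
  model <- build_backbone(64L, num_classes, topology, seed = seed)
  model$features <- c(stem$layers, model$features)
  model$input_channels <- 128L
  model$min_input <- model$min_input * 4L
  model
}

## ---- late fusion ---------------------------------------------------------

#' Build the late-fusion classification head
#'
#' The pixel-stream and SIFT-stream feature vectors (512 each for the
#' resnet18 topology) are concatenated into one 1024-dimensional vector and
#' passed through a single fully connected layer.
#'
#' @param feature_dim dimension of each stream's feature vector (default
#'   512).
#' @param num_classes number of output classes (7 for the cloud-type task).
#' @param seed integer seed for weight initialization.
#' @return object of class `siftcnn_fusion_head` with `fused_dim =
#'   2 * feature_dim`.
#' @export
build_fusion_head <- function(feature_dim = 512L, num_classes = 7L,
                              seed = 0L) {
  withr::with_seed(as.integer(seed), {
    structure(list(linear = nn_linear(2L * feature_dim, num_classes),
                   feature_dim = as.integer(feature_dim),
                   fused_dim = 2L * as.integer(feature_dim),
                   num_classes = as.integer(num_classes)),
              class = "siftcnn_fusion_head")
  })
}

#' Late-fusion forward pass
#'
#' Concatenates the two stream features in the fixed order (pixel, SIFT) and
#' applies the fusion head's linear layer.
#'
#' @param pixel_feat,sift_feat numeric vectors of length `feature_dim`, or
#'   matrices `feature_dim x N`.
#' @param head a [build_fusion_head()] object.
#' @return class-score vector (or `num_classes x N` matrix).
#' @export
late_fusion_forward <- function(pixel_feat, sift_feat, head) {
  pv <- if (is.matrix(pixel_feat)) pixel_feat else matrix(pixel_feat)
  sv <- if (is.matrix(sift_feat)) sift_feat else matrix(sift_feat)
  if (nrow(pv) != head$feature_dim || nrow(sv) != head$feature_dim) {
    stop("shape error: stream features must have length ", head$feature_dim)
  }
  if (ncol(pv) != ncol(sv)) stop("shape error: stream batch sizes differ")
  fused <- rbind(pv, sv)
  scores <- head$linear$params$W %*% fused + head$linear$params$b
  if (ncol(scores) == 1L) drop(scores) else scores
}

#' Build a jointly trainable late-fusion model
#'
#' Couples a pixel backbone and a SIFT backbone with a fusion head; both
#' streams and the head train end-to-end with [train_classifier()], fed with
#' `list(pixel = ..., sift = ...)` input tensors.
#'
#' @param pixel_model,sift_model `siftcnn_model` objects with equal
#'   `feature_dim`.
#' @param num_classes number of output classes.
#' @param seed seed for the fusion-head initialization.
#' @return object of class `siftcnn_fusion`.
#' @export
build_fusion_model <- function(pixel_model, sift_model, num_classes,
                               seed = 0L) {
  stopifnot(pixel_model$feature_dim == sift_model$feature_dim)
  head <- build_fusion_head(pixel_model$feature_dim, num_classes, seed)
  structure(list(pixel = pixel_model, sift = sift_model, head = head,
                 num_classes = as.integer(num_classes),
                 feature_dim = pixel_model$feature_dim),
            class = "siftcnn_fusion")
}

fusion_forward <- function(model, x, training = FALSE) {
  stopifnot(is.list(x), all(c("pixel", "sift") %in% names(x)))
  fp <- seq_forward(model$pixel$features, x$pixel, training)
  fs <- seq_forward(model$sift$features, x$sift, training)
  model$pixel$features <- fp$layers
  model$sift$features <- fs$layers
  fused <- rbind(fp$y, fs$y)
  h <- layer_forward(model$head$linear, fused, training)
  list(scores = h$y,
       caches = list(pixel = fp$caches, sift = fs$caches, head = h$cache),
       model = model)
}

fusion_backward <- function(model, caches, dscores) {
  hb <- layer_backward(model$head$linear, caches$head, dscores, need_dx = TRUE)
  fd <- model$feature_dim
  dp <- hb$dx[seq_len(fd), , drop = FALSE]
  ds <- hb$dx[fd + seq_len(fd), , drop = FALSE]
  pb <- seq_backward(model$pixel$features, caches$pixel, dp, need_dx = FALSE)
  sb <- seq_backward(model$sift$features, caches$sift, ds, need_dx = FALSE)
  list(pixel = pb$grads, sift = sb$grads, head = hb$grads)
}

fusion_sgd_step <- function(model, grads, state, lr, momentum, wd) {
  model$pixel$features <- sgd_update_layers(model$pixel$features, grads$pixel,
                                            state, lr, momentum, wd, "p")
  model$sift$features <- sgd_update_layers(model$sift$features, grads$sift,
                                           state, lr, momentum, wd, "s")
  hl <- sgd_update_layers(list(model$head$linear), list(grads$head), state,
                          lr, momentum, wd, "h")
  model$head$linear <- hl[[1L]]
  model
}

## ---- SVM on features -----------------------------------------------------

#' SVM-on-features specification
#'
#' @param kernel `"linear"` or `"rbf"`.
#' @param cost_grid regularization values searched by cross-validation.
#' @param gamma_grid RBF kernel widths (ignored for the linear kernel).
#' @param cv_folds number of cross-validation folds (5, the protocol used
#'   for model selection on training data).
#' @return object of class `svm_spec`.
#' @export
svm_spec <- function(kernel = c("linear", "rbf"),
                     cost_grid = 10^seq(-2, 2),
                     gamma_grid = NULL,
                     cv_folds = 5L) {
  structure(list(kernel = match.arg(kernel),
                 cost_grid = sort(as.numeric(cost_grid)),
                 gamma_grid = gamma_grid,
                 cv_folds = as.integer(cv_folds)),
            class = "svm_spec")
}

# Seeded stratified fold assignment; errors when a class has fewer samples
# than folds.
stratified_folds <- function(labels, k, seed) {
  folds <- integer(length(labels))
  withr::with_seed(as.integer(seed), {
    for (cl in unique(labels)) {
      ix <- which(labels == cl)
      if (length(ix) < k) {
        stop("stratification error: class ", cl, " has ", length(ix),
             " samples but ", k, " folds are required")
      }
      folds[ix] <- sample(rep_len(seq_len(k), length(ix)))
    }
  })
  folds
}

#' Fit an SVM on backbone features with cross-validated model selection
#'
#' Selects the hyperparameter grid point maximizing mean k-fold
#' cross-validation accuracy on the training features (ties broken toward
#' the smallest cost, then the smallest gamma), then refits on all training
#' data. Deterministic given `seed`.
#'
#' @param features numeric matrix `n x d`.
#' @param labels vector of class labels (any type; coerced to factor).
#' @param spec an [svm_spec()].
#' @param seed integer seed governing the fold assignment.
#' @return object of class `siftcnn_svm` with the fitted `e1071::svm` model,
#'   the selected hyperparameters and the CV table.
#' @export
fit_svm_on_features <- function(features, labels, spec = svm_spec(),
                                seed = 0L) {
  features <- as.matrix(features)
  y <- factor(labels)
  folds <- stratified_folds(as.integer(y), spec$cv_folds, seed)
  grid <- if (spec$kernel == "rbf") {
    gg <- spec$gamma_grid %||% (1 / ncol(features))
    expand.grid(cost = spec$cost_grid, gamma = sort(as.numeric(gg)))
  } else {
    data.frame(cost = spec$cost_grid)
  }
  grid$cv_accuracy <- NA_real_
  for (g in seq_len(nrow(grid))) {
    acc <- numeric(spec$cv_folds)
    for (f in seq_len(spec$cv_folds)) {
      tr <- folds != f
      fit <- if (spec$kernel == "rbf") {
        e1071::svm(features[tr, , drop = FALSE], y[tr], kernel = "radial",
                   cost = grid$cost[g], gamma = grid$gamma[g], scale = FALSE)
      } else {
        e1071::svm(features[tr, , drop = FALSE], y[tr], kernel = "linear",
                   cost = grid$cost[g], scale = FALSE)
      }
      pred <- predict(fit, features[!tr, , drop = FALSE])
      acc[f] <- mean(pred == y[!tr])
    }
    grid$cv_accuracy[g] <- mean(acc)
  }
  # argmax with ties toward smallest cost (grid is sorted cost-fastest)
  best <- which(grid$cv_accuracy >= max(grid$cv_accuracy) - 1e-12)[1L]
  final <- if (spec$kernel == "rbf") {
    e1071::svm(features, y, kernel = "radial", cost = grid$cost[best],
               gamma = grid$gamma[best], scale = FALSE)
  } else {
    e1071::svm(features, y, kernel = "linear", cost = grid$cost[best],
               scale = FALSE)
  }
  structure(list(model = final, best_cost = grid$cost[best],
                 best_gamma = if (spec$kernel == "rbf") grid$gamma[best] else NULL,
                 cv_table = grid, spec = spec, levels = levels(y)),
            class = "siftcnn_svm")
}

#' @export
predict.siftcnn_svm <- function(object, newdata, ...) {
  predict(object$model, as.matrix(newdata), ...)
}

## ---- temporal aggregation ------------------------------------------------

#' Aggregate a sequence of frame feature vectors
#'
#' Maps a variable-length sequence of equal-length feature vectors to one
#' fixed-length vector. The default aggregator is temporal mean pooling; any
#' sequence encoder with the same signature (matrix in, vector out) can be
#' substituted.
#'
#' @param frame_feats matrix `T x d` (rows = frames) or list of length-`d`
#'   vectors.
#' @param aggregator function taking the `T x d` matrix, returning a vector.
#' @return numeric vector of length `d`.
#' @export
temporal_aggregate <- function(frame_feats, aggregator = colMeans) {
  if (is.list(frame_feats)) {
    if (length(frame_feats) == 0L) {
      stop("empty input: need at least one frame feature vector")
    }
    len <- unique(vapply(frame_feats, length, 1L))
    if (length(len) != 1L) stop("all frame features must have equal length")
    frame_feats <- do.call(rbind, frame_feats)
  }
  if (!is.matrix(frame_feats) || nrow(frame_feats) == 0L) {
    stop("empty input: need at least one frame feature vector")
  }
  aggregator(frame_feats)
}
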