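# Compact CNN engine on base R + BLAS.
#
# Tensors are 4-D arrays (H, W, C, N). Convolution and max pooling are
# implemented as im2col indexing plus matrix multiplication; backward passes
# are exact gradients. Layers are plain lists; a forward pass returns the
# output, a cache for the backward pass, and (in training mode) the layer
# with updated batch-norm running statistics.

`%||%` <- function(a, b) if (is.null(a)) b else a

.nn_cache <- new.env(parent = emptyenv())

# im2col index matrix for a (Hp, Wp, C) padded volume, kernel (kh, kw),
# stride s: (kh*kw*C) x (Ho*Wo), 1-based linear indices, patch ordered
# (ki fastest, then kj, then channel), outputs ordered column-major (oh
# fastest). Cached by shape.
im2col_index <- function(Hp, Wp, C, kh, kw, s) {
  key <- paste(Hp, Wp, C, kh, kw, s, sep = "_")
  hit <- .nn_cache[[key]]
  if (!is.null(hit)) return(hit)
  Ho <- (Hp - kh) %/% s + 1L
  Wo <- (Wp - kw) %/% s + 1L
  ki <- rep(seq_len(kh), times = kw * C)
  kj <- rep(rep(seq_len(kw), each = kh), times = C)
  cc <- rep(seq_len(C), each = kh * kw)
  patch <- (ki - 1L) + (kj - 1L) * Hp + (cc - 1L) * (Hp * Wp)
  oh <- rep(seq.int(0L, Ho - 1L), times = Wo) * s
  ow <- rep(seq.int(0L, Wo - 1L), each = Ho) * s
  base <- oh + ow * Hp
  M <- outer(patch, base, "+") + 1
  res <- list(M = M, Ho = Ho, Wo = Wo)
  .nn_cache[[key]] <- res
  res
}

pad_tensor <- function(x, p, value = 0) {
  if (p == 0L) return(x)
  d <- dim(x)
  out <- array(value, dim = c(d[1L] + 2L * p, d[2L] + 2L * p, d[3L], d[4L]))
  out[(p + 1L):(p + d[1L]), (p + 1L):(p + d[2L]), , ] <- x
  out
}

## ---- layer constructors -------------------------------------------------

nn_conv <- function(cin, cout, k, stride = 1L, pad = 0L) {
  fan_in <- k * k * cin
  W <- matrix(stats::rnorm(cout * fan_in, sd = sqrt(2 / fan_in)), cout, fan_in)
  list(type = "conv", cin = cin, cout = cout, k = as.integer(k),
       stride = as.integer(stride), pad = as.integer(pad),
       params = list(W = W, b = numeric(cout)))
}

nn_bn <- function(c, eps = 1e-5, momentum = 0.1) {
  list(type = "bn", c = c, eps = eps, momentum = momentum,
       params = list(gamma = rep(1, c), beta = numeric(c)),
       run_mean = numeric(c), run_var = rep(1, c))
}

nn_relu <- function() list(type = "relu")

nn_maxpool <- function(k = 3L, stride = 2L, pad = 1L) {
  list(type = "maxpool", k = as.integer(k), stride = as.integer(stride),
       pad = as.integer(pad))
}

nn_gap <- function() list(type = "gap")

nn_linear <- function(cin, cout) {
  W <- matrix(stats::rnorm(cout * cin, sd = sqrt(2 / cin)), cout, cin)
  list(type = "linear", cin = cin, cout = cout,
       params = list(W = W, b = numeric(cout)))
}

nn_block <- function(main, down = NULL) {
  list(type = "block", main = main, down = down)
}

## ---- forward / backward -------------------------------------------------

conv_forward <- function(layer, x) {
  d <- dim(x)
  xp <- pad_tensor(x, layer$pad)
  dp <- dim(xp)
  ii <- im2col_index(dp[1L], dp[2L], dp[3L], layer$k, layer$k, layer$stride)
  n <- d[4L]
  offs <- (seq_len(n) - 1) * (dp[1L] * dp[2L] * dp[3L])
  # flatten: a matrix index into a 4-D array would be read as coordinates
  idx <- as.vector(outer(as.vector(ii$M), offs, "+"))
  cols <- xp[idx]
  dim(cols) <- c(nrow(ii$M), ii$Ho * ii$Wo * n)
  Y <- layer$params$W %*% cols + layer$params$b
  y <- aperm(array(Y, c(layer$cout, ii$Ho, ii$Wo, n)), c(2L, 3L, 1L, 4L))
  list(y = y, cache = list(cols = cols, ii = ii, dp = dp, d = d, offs = offs))
}

conv_backward <- function(layer, cache, dy, need_dx = TRUE) {
  ii <- cache$ii; d <- cache$d; dp <- cache$dp
  n <- d[4L]
  dY <- aperm(dy, c(3L, 1L, 2L, 4L))
  dim(dY) <- c(layer$cout, ii$Ho * ii$Wo * n)
  gW <- dY %*% t(cache$cols)
  gb <- rowSums(dY)
  dx <- NULL
  if (need_dx) {
    dcols <- crossprod(layer$params$W, dY)
    dxp <- numeric(prod(dp[1:3]) * n)
    kh <- layer$k; kw <- layer$k; C <- layer$cin
    for (kj in seq_len(kw)) {
      for (ki in seq_len(kh)) {
        sel <- (seq_len(C) - 1L) * (kh * kw) + (kj - 1L) * kh + ki
        idx <- as.vector(outer(as.vector(ii$M[sel, , drop = FALSE]),
                               cache$offs, "+"))
        dxp[idx] <- dxp[idx] + as.vector(dcols[sel, , drop = FALSE])
      }
    }
    dim(dxp) <- c(dp[1:3], n)
    p <- layer$pad
    dx <- if (p > 0L) {
      dxp[(p + 1L):(p + d[1L]), (p + 1L):(p + d[2L]), , , drop = FALSE]
    } else dxp
  }
  list(dx = dx, grads = list(W = gW, b = gb))
}

bn_forward <- function(layer, x, training) {
  d <- dim(x)
  xm <- aperm(x, c(1L, 2L, 4L, 3L))
  dim(xm) <- c(d[1L] * d[2L] * d[4L], d[3L])
  if (training) {
    mu <- colMeans(xm)
    va <- colMeans(xm * xm) - mu * mu
    layer$run_mean <- (1 - layer$momentum) * layer$run_mean + layer$momentum * mu
    layer$run_var <- (1 - layer$momentum) * layer$run_var + layer$momentum * va
  } else {
    mu <- layer$run_mean
    va <- layer$run_var
  }
  istd <- 1 / sqrt(va + layer$eps)
  xhat <- sweep(xm, 2L, mu, "-")
  xhat <- sweep(xhat, 2L, istd, "*")
  ym <- sweep(xhat, 2L, layer$params$gamma, "*")
  ym <- sweep(ym, 2L, layer$params$beta, "+")
  dim(ym) <- c(d[1L], d[2L], d[4L], d[3L])
  y <- aperm(ym, c(1L, 2L, 4L, 3L))
  list(y = y, cache = list(xhat = xhat, istd = istd, d = d, training = training),
       layer = layer)
}

bn_backward <- function(layer, cache, dy, need_dx = TRUE) {
  d <- cache$d
  dym <- aperm(dy, c(1L, 2L, 4L, 3L))
  dim(dym) <- c(d[1L] * d[2L] * d[4L], d[3L])
  m <- nrow(dym)
  dgamma <- colSums(dym * cache$xhat)
  dbeta <- colSums(dym)
  dx <- NULL
  if (need_dx) {
    if (cache$training) {
      t1 <- sweep(dym, 2L, dbeta / m, "-")
      t2 <- sweep(cache$xhat, 2L, dgamma / m, "*")
      dxm <- sweep(t1 - t2, 2L, layer$params$gamma * cache$istd, "*")
    } else {
      dxm <- sweep(dym, 2L, layer$params$gamma * cache$istd, "*")
    }
    dim(dxm) <- c(d[1L], d[2L], d[4L], d[3L])
    dx <- aperm(dxm, c(1L, 2L, 4L, 3L))
  }
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

maxpool_forward <- function(layer, x) {
  d <- dim(x)
  xp <- pad_tensor(x, layer$pad, value = -Inf)
  dp <- dim(xp)
  ii <- im2col_index(dp[1L], dp[2L], 1L, layer$k, layer$k, layer$stride)
  kk <- layer$k^2L
  cn <- d[3L] * d[4L]
  offs <- (seq_len(cn) - 1) * (dp[1L] * dp[2L])
  idx <- as.vector(outer(as.vector(ii$M), offs, "+"))
  vals <- xp[idx]
  dim(vals) <- c(kk, ii$Ho * ii$Wo * cn)
  best <- vals[1L, ]
  arg <- rep(1L, ncol(vals))
  for (r in 2:kk) {
    upd <- vals[r, ] > best
    best[upd] <- vals[r, upd]
    arg[upd] <- r
  }
  y <- array(best, c(ii$Ho, ii$Wo, d[3L], d[4L]))
  list(y = y, cache = list(arg = arg, ii = ii, dp = dp, d = d, offs = offs))
}

maxpool_backward <- function(layer, cache, dy, need_dx = TRUE) {
  if (!need_dx) return(list(dx = NULL, grads = NULL))
  ii <- cache$ii; d <- cache$d; dp <- cache$dp
  kk <- layer$k^2L
  hw <- ii$Ho * ii$Wo
  dyv <- as.vector(dy)
  dxp <- numeric(dp[1L] * dp[2L] * d[3L] * d[4L])
  Mv <- as.vector(ii$M)
  for (r in seq_len(kk)) {
    sel <- which(cache$arg == r)
    if (length(sel) == 0L) next
    posl <- (sel - 1L) %% hw + 1L
    cn <- (sel - 1L) %/% hw
    tgt <- Mv[(posl - 1L) * kk + r] + cn * (dp[1L] * dp[2L])
    dxp[tgt] <- dxp[tgt] + dyv[sel]
  }
  dim(dxp) <- c(dp[1L], dp[2L], d[3L], d[4L])
  p <- layer$pad
  dx <- if (p > 0L) {
    dxp[(p + 1L):(p + d[1L]), (p + 1L):(p + d[2L]), , , drop = FALSE]
  } else dxp
  list(dx = dx, grads = NULL)
}

layer_forward <- function(layer, x, training = FALSE) {
  switch(layer$type,
    conv = c(conv_forward(layer, x), list(layer = layer)),
    bn = bn_forward(layer, x, training),
    relu = {
      y <- x; y[y < 0] <- 0
      list(y = y, cache = list(mask = x > 0), layer = layer)
    },
    maxpool = c(maxpool_forward(layer, x), list(layer = layer)),
    gap = {
      d <- dim(x)
      y <- matrix(colMeans(matrix(x, d[1L] * d[2L], d[3L] * d[4L])),
                  d[3L], d[4L])
      list(y = y, cache = list(d = d), layer = layer)
    },
    linear = {
      y <- layer$params$W %*% x + layer$params$b
      list(y = y, cache = list(x = x), layer = layer)
    },
    block = {
      fm <- seq_forward(layer$main, x, training)
      layer$main <- fm$layers
      if (!is.null(layer$down)) {
        fd <- seq_forward(layer$down, x, training)
        layer$down <- fd$layers
        short <- fd$y
        dcache <- fd$caches
      } else {
        short <- x
        dcache <- NULL
      }
      s <- fm$y + short
      y <- s; y[y < 0] <- 0
      list(y = y,
           cache = list(main = fm$caches, down = dcache, mask = s > 0),
           layer = layer)
    },
    stop("unknown layer type: ", layer$type)
  )
}

layer_backward <- function(layer, cache, dy, need_dx = TRUE) {
  switch(layer$type,
    conv = conv_backward(layer, cache, dy, need_dx),
    bn = bn_backward(layer, cache, dy, need_dx),
    relu = list(dx = if (need_dx) dy * cache$mask else NULL, grads = NULL),
    maxpool = maxpool_backward(layer, cache, dy, need_dx),
    gap = {
      d <- cache$d
      dx <- if (need_dx) {
        array(rep(as.vector(dy), each = d[1L] * d[2L]) / (d[1L] * d[2L]), d)
      } else NULL
      list(dx = dx, grads = NULL)
    },
    linear = {
      gW <- dy %*% t(cache$x)
      gb <- rowSums(dy)
      dx <- if (need_dx) crossprod(layer$params$W, dy) else NULL
      list(dx = dx, grads = list(W = gW, b = gb))
    },
    block = {
      ds <- dy * cache$mask
      bm <- seq_backward(layer$main, cache$main, ds, need_dx = TRUE)
      if (!is.null(layer$down)) {
        bd <- seq_backward(layer$down, cache$down, ds, need_dx = need_dx)
        dx <- if (need_dx) bm$dx + bd$dx else NULL
        list(dx = dx, grads = list(main = bm$grads, down = bd$grads))
      } else {
        dx <- if (need_dx) bm$dx + ds else NULL
        list(dx = dx, grads = list(main = bm$grads, down = NULL))
      }
    },
    stop("unknown layer type: ", layer$type)
  )
}

seq_forward <- function(layers, x, training = FALSE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    f <- layer_forward(layers[[i]], x, training)
    x <- f$y
    caches[[i]] <- f$cache
    layers[[i]] <- f$layer
  }
  list(y = x, caches = caches, layers = layers)
}

seq_backward <- function(layers, caches, dy, need_dx = FALSE) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    nd <- need_dx || i > 1L
    b <- layer_backward(layers[[i]], caches[[i]], dy, need_dx = nd)
    grads[i] <- list(b$grads)   # [[<- would drop NULL entries
    dy <- b$dx
  }
  list(dx = dy, grads = grads)
}

## ---- loss ---------------------------------------------------------------

# scores: (K, N); labels: 0-based integer vector of length N.
softmax_xent <- function(scores, labels) {
  n <- ncol(scores)
  sh <- sweep(scores, 2L, apply(scores, 2L, max), "-")
  ex <- exp(sh)
  p <- sweep(ex, 2L, colSums(ex), "/")
  tix <- cbind(labels + 1L, seq_len(n))
  loss <- -mean(log(pmax(p[tix], 1e-300)))
  dscores <- p
  dscores[tix] <- dscores[tix] - 1
  list(loss = loss, dscores = dscores / n)
}

## ---- SGD with momentum --------------------------------------------------

sgd_update_layers <- function(layers, grads, state, lr, momentum, wd, prefix) {
  for (i in seq_along(layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    if (layers[[i]]$type == "block") {
      layers[[i]]$main <- sgd_update_layers(layers[[i]]$main, g$main, state,
                                            lr, momentum, wd,
                                            paste0(prefix, i, "m"))
      if (!is.null(layers[[i]]$down)) {
        layers[[i]]$down <- sgd_update_layers(layers[[i]]$down, g$down, state,
                                              lr, momentum, wd,
                                              paste0(prefix, i, "d"))
      }
    } else {
      for (pn in names(layers[[i]]$params)) {
        key <- paste0(prefix, i, pn)
        # weight decay applies to weights, not biases/BN offsets
        decay <- if (pn %in% c("W", "gamma")) wd else 0
        v <- state[[key]] %||% 0
        v <- momentum * v - lr * (g[[pn]] + decay * layers[[i]]$params[[pn]])
        state[[key]] <- v
        layers[[i]]$params[[pn]] <- layers[[i]]$params[[pn]] + v
      }
    }
  }
  layers
}

# Collect all parameter arrays of a layer list into a flat named list.
collect_params <- function(layers, prefix = "") {
  out <- list()
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (l$type == "block") {
      out <- c(out, collect_params(l$main, paste0(prefix, i, "m")))
      if (!is.null(l$down)) {
        out <- c(out, collect_params(l$down, paste0(prefix, i, "d")))
      }
    } else if (!is.null(l$params)) {
      for (pn in names(l$params)) {
        out[[paste0(prefix, i, pn)]] <- l$params[[pn]]
      }
    }
  }
  out
}
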