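#' CNN architecture configuration
#'
#' The small convolutional network: three identical 2D convolutional layers
#' (5 filters of size 5 x 5, stride 2 x 2, valid padding), each followed by
#' batch normalization (before the activation), a rectified-linear activation
#' and 0.1 dropout; then a 100-unit fully connected layer (batch norm, ReLU,
#' 0.5 dropout) feeding a softmax output layer.
#'
#' @param n_conv_layers Number of convolutional layers.
#' @param filters Filters per convolutional layer.
#' @param filter_size Filter height/width.
#' @param stride Stride in both dimensions.
#' @param conv_dropout,dense_dropout Dropout rates.
#' @param dense_units Units in the fully connected layer.
#' @param bn_momentum,bn_epsilon Batch-normalization running-average momentum
#'   and variance floor.
#' @return A `cnn_config` list.
#' @export
cnn_config <- function(n_conv_layers = 3L, filters = 5L, filter_size = 5L,
                       stride = 2L, conv_dropout = 0.1, dense_dropout = 0.5,
                       dense_units = 100L, bn_momentum = 0.9,
                       bn_epsilon = 1e-5) {
  structure(list(n_conv_layers = as.integer(n_conv_layers),
                 filters = as.integer(filters),
                 filter_size = as.integer(filter_size),
                 stride = as.integer(stride),
                 conv_dropout = conv_dropout, dense_dropout = dense_dropout,
                 dense_units = as.integer(dense_units),
                 bn_momentum = bn_momentum, bn_epsilon = bn_epsilon),
            class = "cnn_config")
}

conv_out_dim <- function(n, k, s) (n - k) %/% s + 1L

# patch-gathering index for one sample of an (H, W, C, .) array;
# columns ordered with the output-height index fastest
im2col_index <- function(h, w, c, k, stride) {
  oh <- conv_out_dim(h, k, stride)
  ow <- conv_out_dim(w, k, stride)
  offs <- as.vector(outer(outer(seq_len(k), (seq_len(k) - 1L) * h, "+"),
                          (seq_len(c) - 1L) * h * w, "+"))
  starts <- as.vector(outer((seq_len(oh) - 1L) * stride,
                            (seq_len(ow) - 1L) * stride * h, "+"))
  list(idx = outer(offs, starts, "+"), oh = oh, ow = ow)
}

im2col <- function(arr, idx_info) {
  d <- dim(arr)
  b <- d[4]
  npix <- prod(d[1:3])
  idx <- idx_info$idx
  full <- rep(as.vector(idx), b) + rep((seq_len(b) - 1L) * npix,
                                       each = length(idx))
  matrix(arr[full], nrow = nrow(idx))
}

# scatter-accumulate column gradients back to the input array; for a fixed
# within-patch offset the target pixels are distinct, so each row can be
# accumulated with one vectorized assignment
col2im <- function(dcols, idx_info, in_dim, b) {
  npix <- prod(in_dim)
  dx <- numeric(npix * b)
  idx <- idx_info$idx
  p <- ncol(idx)
  boff <- rep((seq_len(b) - 1L) * npix, each = p)
  for (r in seq_len(nrow(idx))) {
    tgt <- rep(idx[r, ], b) + boff
    dx[tgt] <- dx[tgt] + dcols[r, ]
  }
  array(dx, dim = c(in_dim, b))
}

#' Build the small convolutional network
#'
#' @param input_shape Length-2 integer vector `c(32, T)`.
#' @param n_classes Number of output classes.
#' @param config A [cnn_config()].
#' @param seed Integer seed for the Glorot-uniform initialization of the
#'   convolutional and dense hidden layers. The softmax readout starts at
#'   zero, so an untrained network outputs uniform class probabilities.
#' @return A `ci_cnn` model object; its `shapes` element lists the feature-map
#'   size after every layer.
#' @export
build_cnn <- function(input_shape, n_classes, config = cnn_config(),
                      seed = 0L) {
  stopifnot(length(input_shape) == 2L, n_classes >= 2)
  k <- config$filter_size; s <- config$stride
  h <- input_shape[1]; w <- input_shape[2]; ch <- 1L
  shapes <- list(c(h, w, ch))
  layers <- list()
  withr::with_seed(as.integer(seed), {
    for (l in seq_len(config$n_conv_layers)) {
      if (h < k || w < k) {
        stop(sprintf(
          "convolutional layer %d: input %d x %d is smaller than the %d x %d filter",
          l, h, w, k, k))
      }
      f <- config$filters
      fan_in <- k * k * ch; fan_out <- k * k * f
      lim <- sqrt(6 / (fan_in + fan_out))
      layers[[l]] <- list(
        W = matrix(stats::runif(f * fan_in, -lim, lim), nrow = f),
        b = numeric(f), gamma = rep(1, f), beta = numeric(f),
        run_mean = numeric(f), run_var = rep(1, f),
        in_dim = c(h, w, ch), k = k, stride = s)
      h <- conv_out_dim(h, k, s); w <- conv_out_dim(w, k, s); ch <- f
      shapes[[l + 1L]] <- c(h, w, ch)
    }
    flat <- h * w * ch
    u <- config$dense_units
    lim <- sqrt(6 / (flat + u))
    dense <- list(W = matrix(stats::runif(u * flat, -lim, lim), nrow = u),
                  b = numeric(u), gamma = rep(1, u), beta = numeric(u),
                  run_mean = numeric(u), run_var = rep(1, u))
    # softmax readout starts at zero (uniform output before training);
    # hidden layers carry the Glorot-uniform randomness
    out <- list(W = matrix(0, nrow = n_classes, ncol = u),
                b = numeric(n_classes))
    structure(list(conv = layers, dense = dense, out = out, config = config,
                   input_shape = as.integer(input_shape),
                   n_classes = as.integer(n_classes), shapes = shapes,
                   seed = as.integer(seed),
                   idx_cache = lapply(layers, function(ly)
                     im2col_index(ly$in_dim[1], ly$in_dim[2], ly$in_dim[3],
                                  ly$k, ly$stride))),
              class = c("ci_cnn", "ci_model"))
  })
}

#' Parameter count of a model
#'
#' @param model A `ci_perceptron` or `ci_cnn`.
#' @return Named integer vector of per-layer trainable parameter counts
#'   (weights and biases; batch-norm scale/shift included for the CNN).
#' @export
n_parameters <- function(model) {
  p <- model_params(model)
  vapply(p, length, numeric(1))
}

bn_forward <- function(z, gamma, beta, run_mean, run_var, eps, training) {
  if (training) {
    mu <- rowMeans(z)
    zc <- z - mu
    v <- rowMeans(zc * zc)
  } else {
    mu <- run_mean
    v <- run_var
    zc <- z - mu
  }
  inv_std <- 1 / sqrt(v + eps)
  xhat <- zc * inv_std
  list(y = xhat * gamma + beta, xhat = xhat, inv_std = inv_std,
       mu = mu, v = v)
}

bn_backward <- function(dy, xhat, inv_std, gamma) {
  m <- ncol(dy)
  dgamma <- rowSums(dy * xhat)
  dbeta <- rowSums(dy)
  dxhat <- dy * gamma
  dz <- (inv_std / m) *
    (m * dxhat - rowSums(dxhat) - xhat * rowSums(dxhat * xhat))
  list(dz = dz, dgamma = dgamma, dbeta = dbeta)
}

#' @export
model_prepare.ci_cnn <- function(model, feats, rows) {
  x <- feats$x[rows, , , drop = FALSE]
  d <- dim(x)
  if (d[2] != model$input_shape[1] || d[3] != model$input_shape[2]) {
    stop("feature shape does not match the CNN input shape")
  }
  arr <- aperm(x, c(2, 3, 1))
  dim(arr) <- c(d[2], d[3], 1L, d[1])
  arr
}

#' @export
model_input_subset.ci_cnn <- function(model, x, idx) {
  x[, , , idx, drop = FALSE]
}

#' @export
model_forward.ci_cnn <- function(model, xb, training = FALSE) {
  cfg <- model$config
  b <- dim(xb)[4]
  caches <- vector("list", length(model$conv))
  arr <- xb
  for (l in seq_along(model$conv)) {
    ly <- model$conv[[l]]
    ii <- model$idx_cache[[l]]
    cols <- im2col(arr, ii)
    z <- ly$W %*% cols + ly$b
    bn <- bn_forward(z, ly$gamma, ly$beta, ly$run_mean, ly$run_var,
                     cfg$bn_epsilon, training)
    if (training) {
      model$conv[[l]]$run_mean <- cfg$bn_momentum * ly$run_mean +
        (1 - cfg$bn_momentum) * bn$mu
      model$conv[[l]]$run_var <- cfg$bn_momentum * ly$run_var +
        (1 - cfg$bn_momentum) * bn$v
    }
    a <- pmax(bn$y, 0)
    relu_mask <- bn$y > 0
    if (training && cfg$conv_dropout > 0) {
      drop_mask <- (matrix(stats::runif(length(a)), nrow(a)) >=
                      cfg$conv_dropout) / (1 - cfg$conv_dropout)
      a <- a * drop_mask
    } else {
      drop_mask <- NULL
    }
    caches[[l]] <- list(cols = cols, xhat = bn$xhat, inv_std = bn$inv_std,
                        relu_mask = relu_mask, drop_mask = drop_mask,
                        oh = ii$oh, ow = ii$ow)
    # reshape the (F x oh*ow*B) activation to an (oh, ow, F, B) array
    f <- nrow(a)
    arr <- aperm(array(a, c(f, ii$oh, ii$ow, b)), c(2, 3, 1, 4))
  }
  flat_mat <- caches[[length(caches)]]
  f <- model$config$filters
  last <- arr
  dlast <- dim(last)
  # flatten per sample: (oh, ow, F, B) back to (F * P, B) in layer order
  a_last <- matrix(aperm(last, c(3, 1, 2, 4)), nrow = prod(dlast[1:3]))
  dn <- model$dense
  zd <- dn$W %*% a_last + dn$b
  bnd <- bn_forward(zd, dn$gamma, dn$beta, dn$run_mean, dn$run_var,
                    cfg$bn_epsilon, training)
  if (training) {
    model$dense$run_mean <- cfg$bn_momentum * dn$run_mean +
      (1 - cfg$bn_momentum) * bnd$mu
    model$dense$run_var <- cfg$bn_momentum * dn$run_var +
      (1 - cfg$bn_momentum) * bnd$v
  }
  hd <- pmax(bnd$y, 0)
  relu_d <- bnd$y > 0
  if (training && cfg$dense_dropout > 0) {
    drop_d <- (matrix(stats::runif(length(hd)), nrow(hd)) >=
                 cfg$dense_dropout) / (1 - cfg$dense_dropout)
    hd <- hd * drop_d
  } else {
    drop_d <- NULL
  }
  scores <- model$out$W %*% hd + model$out$b
  probs <- softmax_cols(scores)
  list(probs = t(probs),
       cache = list(conv = caches, flat = a_last, zd_xhat = bnd$xhat,
                    zd_inv_std = bnd$inv_std, relu_d = relu_d,
                    drop_d = drop_d, hd = hd, probs = probs, b = b),
       model = model)
}

#' @export
model_backward.ci_cnn <- function(model, cache, onehot) {
  cfg <- model$config
  b <- cache$b
  grads <- list()
  dscores <- (cache$probs - t(onehot)) / b          # K x B
  grads$out.W <- dscores %*% t(cache$hd)
  grads$out.b <- rowSums(dscores)
  dh <- t(model$out$W) %*% dscores
  if (!is.null(cache$drop_d)) dh <- dh * cache$drop_d
  dh <- dh * cache$relu_d
  bnb <- bn_backward(dh, cache$zd_xhat, cache$zd_inv_std, model$dense$gamma)
  grads$dense.gamma <- bnb$dgamma
  grads$dense.beta <- bnb$dbeta
  grads$dense.W <- bnb$dz %*% t(cache$flat)
  grads$dense.b <- rowSums(bnb$dz)
  dflat <- t(model$dense$W) %*% bnb$dz              # (F*P) x B
  # back to the last conv layer's (F x P*B) matrix form
  lastc <- cache$conv[[length(cache$conv)]]
  f <- cfg$filters
  p <- lastc$oh * lastc$ow
  darr <- array(dflat, c(f, lastc$oh, lastc$ow, b))  # (F, oh, ow, B)
  da <- matrix(aperm(darr, c(1, 2, 3, 4)), nrow = f) # columns: p fast, then b
  for (l in rev(seq_along(model$conv))) {
    ly <- model$conv[[l]]
    cc <- cache$conv[[l]]
    if (!is.null(cc$drop_mask)) da <- da * cc$drop_mask
    da <- da * cc$relu_mask
    bnb <- bn_backward(da, cc$xhat, cc$inv_std, ly$gamma)
    grads[[paste0("conv", l, ".gamma")]] <- bnb$dgamma
    grads[[paste0("conv", l, ".beta")]] <- bnb$dbeta
    grads[[paste0("conv", l, ".W")]] <- bnb$dz %*% t(cc$cols)
    grads[[paste0("conv", l, ".b")]] <- rowSums(bnb$dz)
    if (l > 1L) {
      dcols <- t(ly$W) %*% bnb$dz
      dx_arr <- col2im(dcols, model$idx_cache[[l]], ly$in_dim, b)
      # convert (oh, ow, F, B) input-gradient array to the previous layer's
      # (F x P*B) activation-matrix form
      da <- matrix(aperm(dx_arr, c(3, 1, 2, 4)), nrow = ly$in_dim[3])
    }
  }
  grads
}

#' @export
model_params.ci_cnn <- function(model) {
  p <- list()
  for (l in seq_along(model$conv)) {
    ly <- model$conv[[l]]
    p[[paste0("conv", l, ".W")]] <- ly$W
    p[[paste0("conv", l, ".b")]] <- ly$b
    p[[paste0("conv", l, ".gamma")]] <- ly$gamma
    p[[paste0("conv", l, ".beta")]] <- ly$beta
  }
  p$dense.W <- model$dense$W; p$dense.b <- model$dense$b
  p$dense.gamma <- model$dense$gamma; p$dense.beta <- model$dense$beta
  p$out.W <- model$out$W; p$out.b <- model$out$b
  p
}

#' @export
model_set_params.ci_cnn <- function(model, params) {
  for (l in seq_along(model$conv)) {
    model$conv[[l]]$W <- params[[paste0("conv", l, ".W")]]
    model$conv[[l]]$b <- params[[paste0("conv", l, ".b")]]
    model$conv[[l]]$gamma <- params[[paste0("conv", l, ".gamma")]]
    model$conv[[l]]$beta <- params[[paste0("conv", l, ".beta")]]
  }
  model$dense$W <- params$dense.W; model$dense$b <- params$dense.b
  model$dense$gamma <- params$dense.gamma; model$dense$beta <- params$dense.beta
  model$out$W <- params$out.W; model$out$b <- params$out.b
  model
}
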