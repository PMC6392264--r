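#' Softmax perceptron
#'
#' A flat architecture that classifies each flattened spectrogram directly:
#' `p(Y = i | x) = exp(W_i . x + b_i) / sum_j exp(W_j . x + b_j)`. The
#' trainable parameters are the `K x D` weight matrix `W` and the bias `b`.
#'
#' @param input_dim Length `D` of the flattened input (32 * T).
#' @param n_classes Number of classes `K`.
#' @param seed Integer seed; stored for reproducible tie-breaking (and any
#'   stochastic training the model undergoes). The softmax layer itself is
#'   zero-initialized — the standard starting point for (convex) softmax
#'   regression — so an untrained model outputs exactly uniform class
#'   probabilities and its pre-training guesses are at chance.
#' @return A `ci_perceptron` model object.
#' @export
perceptron <- function(input_dim, n_classes, seed = 0L) {
  stopifnot(input_dim >= 1, n_classes >= 2)
  params <- list(W = matrix(0, nrow = n_classes, ncol = input_dim),
                 b = numeric(n_classes))
  structure(list(params = params, input_dim = as.integer(input_dim),
                 n_classes = as.integer(n_classes), seed = as.integer(seed)),
            class = c("ci_perceptron", "ci_model"))
}

#' Softmax class probabilities
#'
#' Numerically stabilized by max-subtraction, which leaves the value
#' unchanged.
#'
#' @param params A `ci_perceptron`, or a list with elements `W` (`K x D`) and
#'   `b` (length `K`).
#' @param x A length-`D` vector or an `n x D` matrix of inputs.
#' @return A length-`K` probability vector, or an `n x K` matrix; rows sum
#'   to 1.
#' @export
softmax_predict <- function(params, x) {
  if (inherits(params, "ci_perceptron")) params <- params$params
  stopifnot(is.matrix(params$W), length(params$b) == nrow(params$W))
  vec_in <- !is.matrix(x)
  if (vec_in) x <- matrix(x, nrow = 1)
  if (!all(is.finite(x))) stop("non-finite input to softmax_predict")
  scores <- x %*% t(params$W)
  scores <- sweep(scores, 2, params$b, "+")
  p <- softmax_rows(scores)
  if (vec_in) p[1, ] else p
}

# row-wise stabilized softmax
softmax_rows <- function(scores) {
  m <- apply(scores, 1, max)
  e <- exp(scores - m)
  e / rowSums(e)
}

# column-wise stabilized softmax (K x B score matrix)
softmax_cols <- function(scores) {
  m <- apply(scores, 2, max)
  e <- exp(sweep(scores, 2, m, "-"))
  sweep(e, 2, colSums(e), "/")
}

# ---- internal model interface (shared with the CNN) ----------------------

model_prepare <- function(model, feats, rows) UseMethod("model_prepare")
model_input_subset <- function(model, x, idx) UseMethod("model_input_subset")
model_forward <- function(model, xb, training = FALSE) UseMethod("model_forward")
model_backward <- function(model, cache, onehot) UseMethod("model_backward")
model_params <- function(model) UseMethod("model_params")
model_set_params <- function(model, params) UseMethod("model_set_params")

#' @export
model_prepare.ci_perceptron <- function(model, feats, rows) {
  xm <- flatten_features(feats, rows)
  if (ncol(xm) != model$input_dim) {
    stop(sprintf("input length %d does not match model input_dim %d",
                 ncol(xm), model$input_dim))
  }
  xm
}

#' @export
model_input_subset.ci_perceptron <- function(model, x, idx) {
  x[idx, , drop = FALSE]
}

#' @export
model_forward.ci_perceptron <- function(model, xb, training = FALSE) {
  probs <- softmax_predict(model$params, xb)
  if (!is.matrix(probs)) probs <- matrix(probs, nrow = 1)
  list(probs = probs, cache = list(x = xb, probs = probs))
}

#' @export
model_backward.ci_perceptron <- function(model, cache, onehot) {
  b <- nrow(cache$x)
  dscores <- (cache$probs - onehot) / b         # B x K, onehot is B x K
  list(W = t(dscores) %*% cache$x, b = colSums(dscores))
}

#' @export
model_params.ci_perceptron <- function(model) model$params

#' @export
model_set_params.ci_perceptron <- function(model, params) {
  stopifnot(identical(dim(params$W), dim(model$params$W)))
  model$params <- params
  model
}
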