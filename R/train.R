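#' Training configuration
#'
#' Mini-batch gradient descent minimizing categorical cross-entropy, with the
#' step size adjusted by Adadelta and early stopping on the validation error.
#' Defaults mirror the simulation's recipe: learning rate 0.01 for the
#' perceptron (use 0.1 for the CNN), mini-batch size 32, patience 10.
#'
#' @param learning_rate Multiplier on the Adadelta update.
#' @param batch_size Mini-batch size.
#' @param rho,epsilon Adadelta decay rate and conditioning constant.
#' @param patience Early stopping: halt once the monitored validation error
#'   has failed to improve for this many consecutive epochs.
#' @param max_epochs Hard epoch ceiling.
#' @param monitor `"loss"` (validation cross-entropy, the default) or
#'   `"accuracy"` (validation error rate).
#' @param seed Integer seed fixing shuffling and dropout.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 0.01, batch_size = 32L, rho = 0.95,
                         epsilon = 1e-6, patience = 10L, max_epochs = 200L,
                         monitor = c("loss", "accuracy"), seed = 0L) {
  monitor <- match.arg(monitor)
  stopifnot(patience >= 1, batch_size >= 1, max_epochs >= 1)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), rho = rho,
                 epsilon = epsilon, patience = as.integer(patience),
                 max_epochs = as.integer(max_epochs), monitor = monitor,
                 seed = as.integer(seed)),
            class = "train_config")
}

# Adadelta (decaying-average) update; state holds E[g^2] and E[dx^2]
adadelta_step <- function(params, grads, state, config) {
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$eg[[nm]] <- config$rho * state$eg[[nm]] + (1 - config$rho) * g * g
    dx <- -sqrt(state$ed[[nm]] + config$epsilon) /
      sqrt(state$eg[[nm]] + config$epsilon) * g
    state$ed[[nm]] <- config$rho * state$ed[[nm]] + (1 - config$rho) * dx * dx
    params[[nm]] <- params[[nm]] + config$learning_rate * dx
  }
  list(params = params, state = state)
}

cross_entropy <- function(probs, y1) {
  # probs: B x K, y1: 1-based labels
  p <- probs[cbind(seq_along(y1), y1)]
  -mean(log(pmax(p, 1e-12)))
}

# chunked eval-mode forward pass
predict_probs <- function(model, x, n, chunk = 512L) {
  out <- NULL
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    fw <- model_forward(model, model_input_subset(model, x, idx),
                        training = FALSE)
    out <- rbind(out, fw$probs)
  }
  out
}

#' Predict class probabilities for a feature set
#'
#' @param object A trained `ci_perceptron` or `ci_cnn`.
#' @param feats A `ci_features` object.
#' @param rows Optional logical/integer row selector.
#' @param ... Unused.
#' @return An `n x K` matrix of class probabilities.
#' @export
predict.ci_model <- function(object, feats, rows = NULL, ...) {
  if (is.null(rows)) rows <- rep(TRUE, dim(feats$x)[1])
  x <- model_prepare(object, feats, rows)
  n <- if (is.logical(rows)) sum(rows) else length(rows)
  predict_probs(object, x, n)
}

#' Evaluate a model on a labelled set
#'
#' Accuracy is the fraction of correct predictions; the predicted labels are
#' returned in the input order so two models' predictions can be paired
#' item-by-item for randomization testing.
#'
#' @param model A trained model.
#' @param x Prepared input (from `model_prepare`), or a `ci_features` if `y`
#'   is `NULL`.
#' @param y Integer gold labels (0-based), or `NULL` with `split` given.
#' @param split When `x` is a `ci_features`: which split to evaluate.
#' @return List with `accuracy`, `predictions` (0-based labels), and `loss`
#'   (cross-entropy).
#' @details Exact ties in the class probabilities (an untrained
#'   zero-readout model outputs exactly uniform probabilities) are broken by
#'   a uniform draw seeded deterministically from the model's seed and the
#'   input, so repeated evaluations of the same model on the same data give
#'   identical label vectors while an ignorant model still guesses each
#'   item's class at chance.
#' @export
evaluate_model <- function(model, x, y = NULL, split = "test") {
  if (inherits(x, "ci_features") && is.null(y)) {
    rows <- x$split == split
    y <- x$y[rows]
    x <- model_prepare(model, x, rows)
  }
  stopifnot(length(y) >= 1)
  probs <- predict_probs(model, x, length(y))
  pred <- argmax_labels(probs, tie_seed(model, x)) - 1L
  list(accuracy = mean(pred == y),
       predictions = pred,
       loss = cross_entropy(probs, y + 1L))
}

# deterministic seed for tie-breaking: a function of the model seed and an
# input fingerprint, so the same (model, data) pair always draws the same
# guesses while different featurizations draw independently
tie_seed <- function(model, x) {
  v <- as.numeric(x)
  fp <- sum(abs(v[seq_len(min(length(v), 10000L))]))
  s <- if (is.null(model$seed)) 0L else model$seed
  as.integer((fp * 1e4 + as.numeric(s) * 7919) %% 2147483646) + 1L
}

argmax_labels <- function(probs, seed) {
  pred <- max.col(probs, ties.method = "first")
  mx <- probs[cbind(seq_len(nrow(probs)), pred)]
  tied <- rowSums(abs(probs - mx) < 1e-12) > 1L
  if (any(tied)) {
    withr::with_seed(seed, {
      for (i in which(tied)) {
        cand <- which(abs(probs[i, ] - mx[i]) < 1e-12)
        pred[i] <- cand[sample.int(length(cand), 1L)]
      }
    })
  }
  pred
}

#' Train a model with Adadelta mini-batch gradient descent
#'
#' Minimizes categorical cross-entropy. The returned history includes an
#' epoch-0 row evaluated before any parameter update (the "accuracy before
#' training" entry needed for transfer experiments), and the returned model
#' carries the parameters of the best validation epoch. Training halts when
#' the monitored validation error has not improved for `patience` epochs or
#' at `max_epochs`.
#'
#' @param model A `ci_perceptron` or `ci_cnn` (possibly pre-trained: passing
#'   a trained model continues from its parameters).
#' @param feats A `ci_features` with `train` and `val` splits.
#' @param config A [train_config()].
#' @return A `ci_fit`: `model` (best-epoch parameters), `model_epoch1`
#'   (parameters after the first epoch), `history` (data frame with epoch,
#'   train_loss, val_loss, val_accuracy), `best_epoch`, `n_epochs`.
#' @export
train_model <- function(model, feats, config = train_config()) {
  stopifnot(inherits(model, "ci_model"), inherits(feats, "ci_features"))
  tr_rows <- feats$split == "train"
  va_rows <- feats$split == "val"
  if (!any(tr_rows) || !any(va_rows)) {
    stop("train and validation splits must be non-empty")
  }
  x_tr <- model_prepare(model, feats, tr_rows)
  y_tr <- feats$y[tr_rows] + 1L
  x_va <- model_prepare(model, feats, va_rows)
  y_va <- feats$y[va_rows]
  n_tr <- length(y_tr)
  k <- model$n_classes
  if (any(feats$y >= k)) stop("labels exceed the model's class count")

  withr::with_seed(config$seed, {
    state <- list(eg = lapply(model_params(model), function(p) p * 0),
                  ed = lapply(model_params(model), function(p) p * 0))
    ev <- evaluate_model(model, x_va, y_va)
    history <- data.frame(epoch = 0L, train_loss = NA_real_,
                          val_loss = ev$loss, val_accuracy = ev$accuracy)
    metric <- function(e) if (config$monitor == "loss") e$loss else 1 - e$accuracy
    best_metric <- metric(ev)
    best_epoch <- 0L
    best_params <- model_params(model)
    model_epoch1 <- NULL
    epoch <- 0L
    while (epoch < config$max_epochs) {
      epoch <- epoch + 1L
      ord <- sample.int(n_tr)
      losses <- numeric(0)
      for (start in seq(1L, n_tr, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, n_tr)]
        xb <- model_input_subset(model, x_tr, idx)
        yb <- y_tr[idx]
        fw <- model_forward(model, xb, training = TRUE)
        if (!is.null(fw$model)) model <- fw$model
        losses <- c(losses, cross_entropy(fw$probs, yb))
        onehot <- matrix(0, length(yb), k)
        onehot[cbind(seq_along(yb), yb)] <- 1
        grads <- model_backward(model, fw$cache, onehot)
        upd <- adadelta_step(model_params(model), grads, state, config)
        state <- upd$state
        model <- model_set_params(model, upd$params)
      }
      ev <- evaluate_model(model, x_va, y_va)
      history <- rbind(history, data.frame(
        epoch = epoch, train_loss = mean(losses), val_loss = ev$loss,
        val_accuracy = ev$accuracy))
      if (epoch == 1L) model_epoch1 <- model
      if (metric(ev) < best_metric) {
        best_metric <- metric(ev)
        best_epoch <- epoch
        best_params <- model_params(model)
      }
      if (epoch - best_epoch >= config$patience) break
    }
    structure(list(model = model_set_params(model, best_params),
                   model_epoch1 = model_epoch1,
                   history = history, best_epoch = best_epoch,
                   n_epochs = epoch, config = config),
              class = "ci_fit")
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ci_fit <- function(x, ...) {
  cat(sprintf("<ci_fit> %d epochs (best %d), final val accuracy %.3f\n",
              x$n_epochs, x$best_epoch,
              x$history$val_accuracy[nrow(x$history)]))
  invisible(x)
}
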