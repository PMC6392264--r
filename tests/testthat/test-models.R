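test_that("softmax matches the closed form and normalizes", {
  # zero parameters: uniform over K
  m <- perceptron(4, 5)
  p0 <- list(W = matrix(0, 5, 4), b = numeric(5))
  expect_equal(softmax_predict(p0, c(1, 2, 3, 4)), rep(0.2, 5))
  # bias-only closed form
  pb <- list(W = matrix(0, 2, 3), b = c(log(3), 0))
  expect_equal(softmax_predict(pb, c(9, -4, 2)), c(0.75, 0.25))
  # random case equals the naive unstabilized formula
  withr::with_seed(3, {
    W <- matrix(stats::rnorm(12), 3); b <- stats::rnorm(3)
    x <- stats::rnorm(4)
    naive <- exp(W %*% x + b); naive <- naive / sum(naive)
    expect_equal(softmax_predict(list(W = W, b = b), x), as.vector(naive),
                 tolerance = 1e-12)
  })
  # normalization on randomized batches
  withr::with_seed(4, {
    X <- matrix(stats::rnorm(50 * 4, sd = 10), 50)
    P <- softmax_predict(m, X)
    expect_true(all(abs(rowSums(P) - 1) < 1e-9))
  })
  expect_error(softmax_predict(m, c(1, NA, 3, 4)), "non-finite")
})

test_that("CNN layer shapes and parameter counts follow the recipe", {
  m <- build_cnn(c(32, 96), 10)
  expect_equal(m$shapes[[2]], c(14, 46, 5))   # floor((32-5)/2)+1, floor((96-5)/2)+1
  np <- n_parameters(m)
  expect_equal(unname(np["conv1.W"] + np["conv1.b"]), 130)
  expect_error(build_cnn(c(4, 96), 10), "layer 1")
  expect_error(build_cnn(c(32, 9), 10), "layer [0-9]")
})

test_that("CNN forward on zero input with zero readout is uniform", {
  m <- build_cnn(c(32, 40), 4, seed = 1)
  p <- model_params(m)
  p$dense.W[] <- 0; p$dense.b[] <- 0; p$out.W[] <- 0; p$out.b[] <- 0
  m <- model_set_params(m, p)
  fw <- model_forward(m, array(0, c(32, 40, 1, 3)), training = FALSE)
  expect_equal(fw$probs, matrix(0.25, 3, 4))
})

test_that("CNN backprop agrees with numerical gradients", {
  cfg <- cnn_config(n_conv_layers = 2L, filters = 2L, filter_size = 3L,
                    stride = 2L, conv_dropout = 0, dense_dropout = 0,
                    dense_units = 4L)
  m <- build_cnn(c(10, 12), 3, cfg, seed = 5)
  withr::with_seed(11, {
    b <- 4L
    xb <- array(stats::rnorm(10 * 12 * b), c(10, 12, 1, b))
    y <- c(1L, 2L, 3L, 1L)
  })
  onehot <- matrix(0, b, 3); onehot[cbind(seq_len(b), y)] <- 1
  loss_fn <- function(model) {
    fw <- model_forward(model, xb, training = TRUE)
    -mean(log(fw$probs[cbind(seq_len(b), y)]))
  }
  fw <- model_forward(m, xb, training = TRUE)
  gr <- model_backward(m, fw$cache, onehot)
  pp <- model_params(m)
  eps <- 1e-5
  withr::with_seed(12, {
    for (nm in names(pp)) {
      for (ii in sample(length(pp[[nm]]), min(3, length(pp[[nm]])))) {
        p1 <- pp; p1[[nm]][ii] <- p1[[nm]][ii] + eps
        p2 <- pp; p2[[nm]][ii] <- p2[[nm]][ii] - eps
        num <- (loss_fn(model_set_params(m, p1)) -
                  loss_fn(model_set_params(m, p2))) / (2 * eps)
        expect_equal(gr[[nm]][ii], num, tolerance = 1e-3,
                     label = sprintf("grad %s[%d]", nm, ii))
      }
    }
  })
})

test_that("perceptron masters a linearly separable toy problem", {
  feats <- toy_features(n = 60, sep = 2)
  m <- perceptron(20, 2, seed = 3)
  fit <- train_model(m, feats, train_config(learning_rate = 1,
                                            max_epochs = 50, seed = 7))
  tr <- evaluate_model(fit$model, feats, split = "train")
  expect_equal(tr$accuracy, 1)
  # training loss decreases over the early epochs
  tl <- fit$history$train_loss[-1]
  expect_lt(tl[min(5, length(tl))], tl[1])
  # history has an epoch-0 row evaluated before any update
  expect_equal(fit$history$epoch[1], 0L)
  ev0 <- evaluate_model(m, feats, split = "val")
  expect_equal(fit$history$val_accuracy[1], ev0$accuracy)
})

test_that("training is deterministic given the seed", {
  feats <- toy_features()
  m <- perceptron(20, 2, seed = 1)
  cfg <- train_config(max_epochs = 10, seed = 5)
  f1 <- train_model(m, feats, cfg)
  f2 <- train_model(m, feats, cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(model_params(f1$model), model_params(f2$model))
})

test_that("a small CNN trains above chance on the toy problem", {
  feats <- toy_features(n = 90, h = 12, w = 14, sep = 1.5)
  cfg <- cnn_config(n_conv_layers = 2L, filters = 3L, filter_size = 3L,
                    dense_units = 8L)
  m <- build_cnn(c(12, 14), 2, cfg, seed = 2)
  fit <- train_model(m, feats, train_config(learning_rate = 1,
                                            max_epochs = 15, seed = 4))
  expect_gt(evaluate_model(fit$model, feats, split = "train")$accuracy, 0.6)
})

test_that("evaluation returns pairable predictions and exact accuracy", {
  feats <- toy_features()
  m <- perceptron(20, 2, seed = 8)
  ev1 <- evaluate_model(m, feats, split = "test")
  ev2 <- evaluate_model(m, feats, split = "test")
  expect_identical(ev1$predictions, ev2$predictions)
  gold <- feats$y[feats$split == "test"]
  expect_length(ev1$predictions, length(gold))
  # accuracy equals the mean agreement indicator, recomputed by loop
  agree <- vapply(seq_along(gold),
                  function(i) ev1$predictions[i] == gold[i], logical(1))
  expect_equal(ev1$accuracy, mean(agree))
})

test_that("pre-trained parameters transfer across featurizations", {
  feats_a <- toy_features(seed = 1)
  feats_b <- toy_features(seed = 2)   # same 32xT convention, different data
  m <- perceptron(20, 2, seed = 1)
  fit_a <- train_model(m, feats_a, train_config(max_epochs = 5, seed = 1))
  fit_b <- train_model(fit_a$model, feats_b,
                       train_config(max_epochs = 5, seed = 1))
  expect_s3_class(fit_b, "ci_fit")
  bad <- structure(feats_b, class = "ci_features")
  bad$x <- array(0, c(10, 4, 9))
  bad$split <- rep(c("train", "val"), 5)
  bad$y <- rep(0:1, 5)
  expect_error(train_model(fit_a$model, bad, train_config(max_epochs = 2)),
               "input")
})
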