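# Shared fixtures and independent oracles, built in code at test time.

# tiny separable two-class feature set shaped like featurized output
toy_features <- function(n = 60, h = 4, w = 5, sep = 1.5, seed = 1) {
  withr::with_seed(seed, {
    x <- array(0, c(n, h, w))
    y <- rep(0:1, length.out = n)
    for (i in seq_len(n)) {
      x[i, , ] <- matrix(stats::rnorm(h * w, mean = sep * y[i]), h, w)
    }
    structure(list(x = x, y = y,
                   split = rep(c("train", "val", "test"), length.out = n),
                   n_classes = 2L, resolution = "high", n_frames = w,
                   config = NULL),
              class = "ci_features")
  })
}

# static-formant template for synthesis tests
flat_template <- function(duration_s = 1, env_value = 1) {
  word_template(0L,
                list(c(500, 500), c(1500, 1500), c(2500, 2500)),
                cbind(c(0, 1), c(env_value, env_value)),
                duration_s)
}

# nearest-centroid classifier: the independent oracle for generator
# discriminability (fit on the train split, score on the test split)
nearest_centroid_accuracy <- function(feats) {
  tr_rows <- feats$split == "train"
  te_rows <- feats$split == "test"
  xm <- cisim:::flatten_features(feats, NULL)
  cls <- sort(unique(feats$y[tr_rows]))
  cent <- t(vapply(cls, function(k) {
    colMeans(xm[tr_rows & feats$y == k, , drop = FALSE])
  }, numeric(ncol(xm))))
  xte <- xm[te_rows, , drop = FALSE]
  d2 <- outer(rowSums(xte^2), rowSums(cent^2), "+") - 2 * xte %*% t(cent)
  pred <- cls[max.col(-d2, ties.method = "first")]
  mean(pred == feats$y[te_rows])
}

# direct FFT peak-picking: local maxima of the magnitude spectrum in Hz
spectral_peaks_hz <- function(x, sample_rate = 16000, rel_floor = 0.001) {
  sp <- Mod(stats::fft(x))[seq_len(length(x) %/% 2)]
  pk <- which(diff(sign(diff(sp))) == -2) + 1L
  pk <- pk[sp[pk] > max(sp) * rel_floor]
  (pk - 1) * sample_rate / length(x)
}

# random paired-prediction instance for ART tests
random_art_instance <- function(n, k = 2, seed = 0) {
  withr::with_seed(seed, {
    list(gold = sample.int(k, n, replace = TRUE) - 1L,
         a = sample.int(k, n, replace = TRUE) - 1L,
         b = sample.int(k, n, replace = TRUE) - 1L)
  })
}

# central 99% binomial acceptance interval (exact quantiles) for an
# observed proportion of successes out of n
binom99 <- function(p, n) {
  c(stats::qbinom(0.005, n, p), stats::qbinom(0.995, n, p)) / n
}
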