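test_that("mel filterbank centers are increasing, interior, and interleaved", {
  fb16 <- mel_filterbank(16)
  fb32 <- mel_filterbank(32)
  c16 <- attr(fb16, "centers_hz")
  c32 <- attr(fb32, "centers_hz")
  expect_true(all(diff(c16) > 0))
  expect_true(all(diff(c32) > 0))
  expect_gt(c16[1], 200); expect_lt(c16[16], 7000)
  expect_gt(c32[1], 200); expect_lt(c32[32], 7000)
  expect_true(all(rowSums(fb16) > 0))
  expect_true(all(rowSums(fb32) > 0))
  # coverage: every FFT bin strictly inside the band has filter weight
  cfg <- feat_config()
  bin_hz <- (seq_len(cfg$fft_length / 2 + 1) - 1) * cfg$sample_rate / cfg$fft_length
  inside <- bin_hz > 200 & bin_hz < 7000
  expect_true(all(colSums(fb32)[inside] > 0))
  expect_error(mel_filterbank(16, feat_config(fmax_hz = 9000)), "Nyquist")
})

test_that("spectrogram geometry and linearity", {
  w <- rep(0, 16000)
  s0 <- compute_spectrogram(w, 32)
  expect_equal(dim(s0$values), c(32L, 96L))
  expect_true(all(s0$values == 0))
  expect_error(compute_spectrogram(rep(0, 700), 32), "window")
  # pure tone lands in the channel nearest its frequency at every frame
  tone <- sin(2 * pi * 1000 * (0:15999) / 16000)
  st <- compute_spectrogram(tone, 32)
  nearest <- which.min(abs(st$channel_centers_hz - 1000))
  expect_true(all(apply(st$values, 2, which.max) == nearest))
  expect_true(all(st$values >= 0))
})

test_that("channel interaction matches its stated row formula", {
  m <- matrix(c(1, 0, 2, 1, 4, 2), nrow = 3, byrow = TRUE)
  expect_equal(apply_channel_interaction(m),
               matrix(c(3, 1, 7, 3, 6, 3), nrow = 3, byrow = TRUE))
  z <- matrix(0, 16, 4)
  expect_equal(apply_channel_interaction(z), z)
  expect_error(apply_channel_interaction(matrix(1, 1, 3)), "2 channels")
})

test_that("channel interaction equals the tridiagonal matrix operator", {
  tri <- cisim:::channel_interaction_matrix(16)
  withr::with_seed(7, {
    for (i in 1:20) {
      x <- matrix(stats::runif(16 * 20), 16, 20)
      expect_equal(apply_channel_interaction(x), tri %*% x, tolerance = 1e-15)
    }
  })
})

test_that("summed-row mass identity holds", {
  withr::with_seed(8, {
    x <- matrix(stats::runif(16 * 30), 16, 30)
    low <- apply_channel_interaction(x)
    expect_equal(sum(low), 3 * sum(x) - sum(x[1, ]) - sum(x[16, ]))
  })
})

test_that("row duplication doubles rows, mass, and refuses to repeat", {
  w <- stats::rnorm(16000)
  med <- compute_spectrogram(w, 16, resolution_tag = "med")
  dup <- duplicate_rows(med)
  expect_equal(nrow(dup$values), 32L)
  expect_equal(dup$values[seq(1, 31, 2), ], dup$values[seq(2, 32, 2), ])
  expect_equal(dup$values[seq(1, 31, 2), ], med$values)
  expect_equal(sum(dup$values), 2 * sum(med$values))
  expect_equal(dup$channel_centers_hz, rep(med$channel_centers_hz, each = 2))
  expect_error(duplicate_rows(dup), "16-channel")
})

test_that("featurize composes the stages in the documented order", {
  withr::with_seed(9, w <- stats::rnorm(16000, sd = 0.1))
  hi <- featurize(w, "high")
  me <- featurize(w, "med")
  lo <- featurize(w, "low")
  for (s in list(hi, me, lo)) {
    expect_equal(dim(s$values), c(32L, 96L))
    expect_true(all(s$values >= 0))
  }
  # med has pairwise-equal rows
  expect_equal(me$values[seq(1, 31, 2), ], me$values[seq(2, 32, 2), ])
  # low row-pair k equals the tridiagonal combination of med rows, before
  # duplication: e.g. pair 3 = med rows 2 + 3 + 4
  med16 <- me$values[seq(1, 31, 2), ]
  expect_equal(lo$values[5, ], med16[2, ] + med16[3, ] + med16[4, ])
  expect_equal(lo$values[6, ], lo$values[5, ])
  expect_equal(lo$values[1, ], med16[1, ] + med16[2, ])
  # determinism
  expect_identical(featurize(w, "low")$values, lo$values)
})

test_that("interaction is rejected on duplicated or high-res spectrograms", {
  w <- stats::rnorm(16000)
  hi <- featurize(w, "high")
  expect_error(apply_channel_interaction(hi), "medium")
  me <- featurize(w, "med")
  expect_error(apply_channel_interaction(me), "duplication")
})

test_that("vectorize flattens row-major by channel and round-trips", {
  m <- matrix(c(1, 2, 3, 4), 2, byrow = TRUE)
  expect_equal(vectorize(m), c(1, 2, 3, 4))
  withr::with_seed(2, x <- matrix(stats::rnorm(32 * 96), 32))
  v <- vectorize(x)
  expect_length(v, 3072L)
  expect_equal(matrix(v, 32, byrow = TRUE), x)
  # element (n-1)*T + t equals x[n, t]
  expect_equal(v[(5 - 1) * 96 + 17], x[5, 17])
})

test_that("corpus featurization pads to a common frame count", {
  co <- make_gender_corpus(12, seed = 4)
  f <- featurize_corpus(co, "high", n_frames = 150)
  expect_equal(dim(f$x)[2:3], c(32L, 150L))
  xm <- cisim:::flatten_features(f, NULL)
  expect_equal(xm[3, ], vectorize(f$x[3, , ]))
})
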