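test_that("synthesis is deterministic and respects the envelope", {
  prof <- speaker_profile(120, 1, 0.02)
  tmpl <- flat_template()
  w1 <- synthesize_utterance(prof, tmpl, seed = 42)
  w2 <- synthesize_utterance(prof, tmpl, seed = 42)
  expect_identical(w1, w2)
  expect_length(w1, 16000L)
  expect_true(all(is.finite(w1)))
  expect_equal(max(abs(w1)), 0.5)

  silent <- word_template(0L, list(c(500, 500), c(1500, 1500)),
                          cbind(c(0, 1), c(0, 0)), 1)
  expect_equal(synthesize_utterance(prof, silent, seed = 1), rep(0, 16000))
})

test_that("an unjittered harmonic source has peaks only at f0 multiples", {
  prof <- speaker_profile(120, 1, 0)
  w <- synthesize_utterance(prof, flat_template(), seed = 3)
  peaks <- spectral_peaks_hz(w)
  # every spectral local maximum sits within 1 bin (1 Hz here) of a
  # multiple of 120 Hz
  offset <- abs(((peaks %% 120) + 60) %% 120 - 60)
  expect_true(all(offset <= 1))
  expect_true(any(abs(peaks - 120) <= 1))
})

test_that("formants above Nyquist after vocal-tract scaling are rejected", {
  prof <- speaker_profile(120, vtl_scale = 1.2, jitter_sd = 0)
  tmpl <- word_template(0L, list(c(500, 500), c(7200, 7200)),
                        cbind(c(0, 1), c(1, 1)), 1)
  expect_error(synthesize_utterance(prof, tmpl, seed = 1), "Nyquist")
})

test_that("template and profile invariants are enforced", {
  expect_error(speaker_profile(-10), "f0_hz")
  expect_error(word_template(0L, list(c(500, 500)), cbind(c(0, 1), c(1, 1)), 1))
  expect_error(word_template(0L, list(c(500, 500), c(9000, 9000)),
                             cbind(c(0, 1), c(1, 1)), 1), "8000")
  expect_error(word_template(0L, list(c(500, 500), c(1500, 1500)),
                             cbind(c(0, 1), c(2, 1)), 1), "\\[0, 1\\]")
})

test_that("gender corpus has exact class counts, splits, and durations", {
  co <- make_gender_corpus(100, male_fraction = 0.7, seed = 5)
  expect_s3_class(co, "ci_corpus")
  expect_equal(sum(co$labels == 0L), 70L)
  expect_equal(sum(co$labels == 1L), 30L)
  expect_equal(unname(table(co$split)[c("train", "val", "test")]),
               array(c(60L, 20L, 20L)), ignore_attr = TRUE)
  lens <- lengths(co$waveforms)
  expect_true(all(lens >= 16000 & lens <= 48000))
  expect_true(all(vapply(co$waveforms,
                         function(w) all(is.finite(w)) && max(abs(w)) <= 0.5,
                         logical(1))))
})

test_that("equal seeds give identical corpora; degenerate classes error", {
  c1 <- make_gender_corpus(20, seed = 9)
  c2 <- make_gender_corpus(20, seed = 9)
  expect_identical(c1$labels, c2$labels)
  expect_identical(c1$waveforms, c2$waveforms)
  c3 <- make_gender_corpus(20, seed = 10)
  expect_false(identical(c1$waveforms, c3$waveforms))
  expect_error(make_gender_corpus(10, male_fraction = 0.01), "class")
})

test_that("word corpus is balanced, fixed-length, and procedural in K", {
  co <- make_word_corpus(10, n_classes = 2, seed = 1)
  expect_true(all(co$labels %in% 0:1))
  expect_true(all(table(co$labels) >= 4))
  expect_true(all(lengths(co$waveforms) == 16000L))
  # template generation never fails for any class count up to 30
  co30 <- make_word_corpus(30, n_classes = 30, seed = 2)
  expect_setequal(unique(co30$labels), 0:29)
})

test_that("gender corpus carries class structure a nearest-centroid oracle finds", {
  co <- make_gender_corpus(300, seed = 11)
  acc <- nearest_centroid_accuracy(featurize_corpus(co, "high",
                                                    normalize = FALSE))
  expect_gt(acc, 0.5)
})

test_that("collapsing resolution reduces oracle accuracy on most seeds", {
  # fine-cue sensitivity: the channel-interaction featurization must lose
  # class-discriminative detail relative to the 32-channel one; the oracle
  # probes the featurization's native (raw-amplitude) information content
  wins <- 0L
  for (s in 0:4) {
    co <- make_gender_corpus(300, seed = s)
    hi <- nearest_centroid_accuracy(featurize_corpus(co, "high",
                                                     normalize = FALSE))
    lo <- nearest_centroid_accuracy(featurize_corpus(co, "low",
                                                     normalize = FALSE))
    wins <- wins + (hi > lo)
  }
  expect_gte(wins, 4L)
})

test_that("word corpus beats chance under the nearest-centroid oracle", {
  co <- make_word_corpus(240, n_classes = 6, seed = 3)
  acc <- nearest_centroid_accuracy(featurize_corpus(co, "high",
                                                    normalize = FALSE))
  expect_gt(acc, 1 / 6)
})
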