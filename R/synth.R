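#' @title Synthetic speech with controllable spectral cues
#'
#' @description
#' The generator emulates the two cue families that distinguish speech classes
#' for normally hearing listeners versus cochlear-implant users: fine-grained
#' spectral cues (fundamental-frequency harmonics, formant center frequencies,
#' vocal-tract-length scaling) and coarse-grained cues (the overall amplitude
#' envelope). Each utterance is a harmonic source shaped by formant resonances
#' and an amplitude envelope — the simplest acoustic model that carries both
#' cue types.
#'
#' @name synthetic-speech
NULL

SAMPLE_RATE <- 16000L

#' Speaker profile
#'
#' @param f0_hz Fundamental frequency in Hz (> 0).
#' @param vtl_scale Multiplicative scaling of formant frequencies, modelling
#'   vocal tract length (> 0; shorter tracts give values > 1).
#' @param jitter_sd Per-utterance relative perturbation (s.d.) applied to f0
#'   and formants (>= 0).
#' @return A `speaker_profile` object.
#' @export
speaker_profile <- function(f0_hz, vtl_scale = 1, jitter_sd = 0) {
  stopifnot(is.numeric(f0_hz), f0_hz > 0,
            is.numeric(vtl_scale), vtl_scale > 0,
            is.numeric(jitter_sd), jitter_sd >= 0)
  structure(list(f0_hz = f0_hz, vtl_scale = vtl_scale, jitter_sd = jitter_sd),
            class = "speaker_profile")
}

#' Word template
#'
#' A class prototype: formant trajectories (linear in time) plus a
#' piecewise-linear amplitude envelope.
#'
#' @param class_id Integer class label (0-based).
#' @param formant_tracks List of length-2 numeric vectors `c(start_hz, end_hz)`
#'   for at least two formants; all frequencies in (0, 8000) Hz.
#' @param envelope_breakpoints Two-column matrix: column 1 is time as a
#'   fraction of the utterance in `[0, 1]` (increasing, starting at 0 and
#'   ending at 1), column 2 the envelope value in `[0, 1]`.
#' @param duration_s Utterance duration in seconds (> 0).
#' @return A `word_template` object.
#' @export
word_template <- function(class_id, formant_tracks, envelope_breakpoints,
                          duration_s) {
  stopifnot(length(class_id) == 1L, class_id >= 0,
            is.list(formant_tracks), length(formant_tracks) >= 2L,
            is.matrix(envelope_breakpoints), ncol(envelope_breakpoints) == 2L,
            is.numeric(duration_s), duration_s > 0)
  freqs <- unlist(formant_tracks)
  if (any(freqs <= 0) || any(freqs >= 8000)) {
    stop("formant frequencies must lie in (0, 8000) Hz")
  }
  ev <- envelope_breakpoints[, 2]
  if (any(ev < 0) || any(ev > 1)) stop("envelope values must lie in [0, 1]")
  tv <- envelope_breakpoints[, 1]
  if (tv[1] != 0 || tv[length(tv)] != 1 || is.unsorted(tv)) {
    stop("envelope times must increase from 0 to 1")
  }
  structure(list(class_id = as.integer(class_id),
                 formant_tracks = formant_tracks,
                 envelope_breakpoints = envelope_breakpoints,
                 duration_s = duration_s),
            class = "word_template")
}

#' Synthesize one utterance
#'
#' Generates a harmonic series at the (jittered) fundamental, shapes each
#' harmonic by Gaussian resonance gains that follow the template's formant
#' tracks scaled by the speaker's vocal-tract factor, applies the amplitude
#' envelope, and normalizes the peak.
#'
#' @param profile A [speaker_profile()].
#' @param template A [word_template()].
#' @param seed Integer; fixes all randomness (jitter, harmonic phases).
#' @param peak Peak amplitude of the output (default 0.5).
#' @param sample_rate Sampling rate in Hz (default 16000).
#' @return Numeric vector of `duration_s * sample_rate` samples.
#' @export
synthesize_utterance <- function(profile, template, seed, peak = 0.5,
                                 sample_rate = SAMPLE_RATE) {
  stopifnot(inherits(profile, "speaker_profile"),
            inherits(template, "word_template"))
  nyquist <- sample_rate / 2
  scaled_max <- max(unlist(template$formant_tracks)) * profile$vtl_scale
  if (scaled_max >= nyquist) {
    stop(sprintf(
      "formant at %.0f Hz after vocal-tract scaling is at or above the Nyquist frequency (%.0f Hz)",
      scaled_max, nyquist))
  }
  n <- round(template$duration_s * sample_rate)
  withr::with_seed(as.integer(seed), {
    jit_f0 <- stats::rnorm(1, 0, profile$jitter_sd)
    jit_formant <- stats::rnorm(length(template$formant_tracks), 0,
                                profile$jitter_sd)
    f0 <- profile$f0_hz * (1 + jit_f0)
    f0 <- max(f0, 1)
    n_harm <- min(floor((nyquist - 1) / f0), 80L)
    if (n_harm < 1L) stop("fundamental frequency above Nyquist")
    phases <- stats::runif(n_harm, 0, 2 * pi)

    tt <- (seq_len(n) - 1) / sample_rate
    # formant gains per harmonic on a coarse grid, then interpolated
    grid <- seq(0, 1, length.out = 50L)
    harm_f <- f0 * seq_len(n_harm)
    gains_grid <- matrix(0.05, nrow = n_harm, ncol = length(grid))
    for (k in seq_along(template$formant_tracks)) {
      trk <- template$formant_tracks[[k]]
      fk <- (trk[1] + (trk[2] - trk[1]) * grid) *
        profile$vtl_scale * (1 + jit_formant[k])
      bw <- pmax(60, 0.07 * fk)
      gains_grid <- gains_grid +
        exp(-0.5 * (outer(harm_f, fk, "-") / rep(bw, each = n_harm))^2)
    }
    tilt <- 1 / seq_len(n_harm)  # source spectral slope
    x <- numeric(n)
    frac <- tt / template$duration_s
    for (h in seq_len(n_harm)) {
      g <- stats::approx(grid, gains_grid[h, ], xout = frac, rule = 2)$y
      x <- x + tilt[h] * g * sin(2 * pi * harm_f[h] * tt + phases[h])
    }
    env <- stats::approx(template$envelope_breakpoints[, 1],
                         template$envelope_breakpoints[, 2],
                         xout = frac, rule = 2)$y
    x <- x * env
    m <- max(abs(x))
    if (m > 0) x <- x * (peak / m)
    x
  })
}

new_corpus <- function(waveforms, labels, split, sample_rate, seed,
                       task = NA_character_) {
  stopifnot(length(waveforms) == length(labels),
            length(labels) == length(split))
  structure(list(waveforms = waveforms, labels = as.integer(labels),
                 split = split, sample_rate = as.integer(sample_rate),
                 seed = seed, task = task),
            class = "ci_corpus")
}

#' @export
print.ci_corpus <- function(x, ...) {
  cat(sprintf("<ci_corpus> %d utterances, %d classes, %d Hz\n",
              length(x$waveforms), length(unique(x$labels)), x$sample_rate))
  cat("  splits:", paste(sprintf("%s=%d", names(table(x$split)),
                                 table(x$split)), collapse = " "), "\n")
  invisible(x)
}

# deterministic 60/20/20 (or custom) split assignment; counts are rounded so
# proportions hold to within one item
assign_splits <- function(n, fractions = c(train = 0.6, val = 0.2, test = 0.2)) {
  n_train <- round(n * fractions[["train"]])
  n_val <- round(n * fractions[["val"]])
  n_test <- n - n_train - n_val
  sample(rep(c("train", "val", "test"), c(n_train, n_val, n_test)))
}

#' Synthetic gender-recognition corpus
#'
#' Binary task emulating male/female speaker classification: the two classes
#' differ strongly in fundamental frequency (low-f0 vs. high-f0 populations)
#' and in vocal-tract-length scaling (the fine-grained cues), while their
#' amplitude-envelope levels overlap heavily (a weakly informative
#' coarse-grained cue). Utterance durations are 1-3 s and the default class
#' imbalance is 70/30, mirroring a multi-speaker read-sentence corpus.
#'
#' @param n_utterances Number of utterances (>= 10).
#' @param male_fraction Fraction assigned to class 0 (default 0.7).
#' @param seed Integer seed; fixes labels, speakers, templates, and splits.
#' @param f0_male,f0_female Mean/s.d. pairs for the two truncated-normal f0
#'   populations, in Hz.
#' @return A `ci_corpus` with labels 0 (male-like) and 1 (female-like) and a
#'   train/val/test split in proportions 60/20/20.
#' @export
make_gender_corpus <- function(n_utterances, male_fraction = 0.7, seed = 0L,
                               f0_male = c(120, 15), f0_female = c(210, 20)) {
  stopifnot(n_utterances >= 10, male_fraction > 0, male_fraction < 1)
  n0 <- round(n_utterances * male_fraction)
  n1 <- n_utterances - n0
  if (n0 == 0L || n1 == 0L) stop("both classes must receive at least one item")
  withr::with_seed(as.integer(seed), {
    labels <- sample(rep(c(0L, 1L), c(n0, n1)))
    split <- assign_splits(n_utterances)
    utt_seeds <- sample.int(.Machine$integer.max - 1L, n_utterances)
    waves <- vector("list", n_utterances)
    for (i in seq_len(n_utterances)) {
      male <- labels[i] == 0L
      f0p <- if (male) f0_male else f0_female
      f0 <- max(60, stats::rnorm(1, f0p[1], f0p[2]))
      vtl <- stats::rnorm(1, if (male) 1.00 else 1.18, 0.04)
      prof <- speaker_profile(f0, max(vtl, 0.5), jitter_sd = 0.02)
      dur <- stats::runif(1, 1, 3)
      tracks <- list(
        c(stats::runif(1, 350, 800), stats::runif(1, 350, 800)),
        c(stats::runif(1, 1000, 2200), stats::runif(1, 1000, 2200)),
        c(stats::runif(1, 2300, 3000), stats::runif(1, 2300, 3000)))
      # overlapping envelope levels: the coarse cue is only weakly informative
      level <- stats::runif(1, if (male) 0.50 else 0.40, if (male) 0.95 else 0.85)
      tb <- c(0, sort(stats::runif(3)), 1)
      ev <- pmin(1, pmax(0.05, level * stats::runif(5, 0.6, 1)))
      tmpl <- word_template(labels[i], tracks, cbind(tb, ev), dur)
      waves[[i]] <- synthesize_utterance(prof, tmpl, utt_seeds[i])
    }
    new_corpus(waves, labels, split, SAMPLE_RATE, as.integer(seed), "gender")
  })
}

# procedural word-class prototypes: distinct formant trajectories and
# envelope shapes per class, deterministic given the template seed
word_class_templates <- function(n_classes, seed) {
  withr::with_seed(as.integer(seed), {
    lapply(seq_len(n_classes) - 1L, function(k) {
      # spread class formants over vowel-like ranges with a golden-ratio
      # offset so classes stay distinct for any n_classes
      u <- ((k * 0.6180339887) %% 1)
      f1 <- 300 + 500 * u + stats::rnorm(1, 0, 20)
      f2 <- 900 + 1400 * ((u + 0.37) %% 1) + stats::rnorm(1, 0, 40)
      f3 <- 2200 + 900 * ((u + 0.71) %% 1) + stats::rnorm(1, 0, 50)
      slope <- stats::runif(3, -0.25, 0.25)
      tracks <- list(c(f1, f1 * (1 + slope[1])),
                     c(f2, f2 * (1 + slope[2])),
                     c(f3, f3 * (1 + slope[3])))
      tb <- c(0, sort(stats::runif(3, 0.15, 0.85)), 1)
      ev <- c(stats::runif(1, 0.05, 0.3), stats::runif(3, 0.3, 1),
              stats::runif(1, 0.05, 0.3))
      word_template(k, tracks, cbind(tb, ev), duration_s = 1)
    })
  })
}

#' Synthetic isolated-word corpus
#'
#' Multi-class task emulating short-command word recognition: each class has a
#' distinct formant-trajectory and envelope prototype; speakers are drawn from
#' a mixed low-/high-f0 pool so speaker identity is uninformative. All
#' utterances are exactly one second long and classes are roughly balanced.
#'
#' @param n_utterances Number of utterances (>= `n_classes`).
#' @param n_classes Number of word classes (>= 2; templates are generated
#'   procedurally, so any reasonable count works).
#' @param seed Integer seed.
#' @param n_speakers Size of the speaker pool (default 24).
#' @return A `ci_corpus` with labels `0 .. n_classes-1`.
#' @export
make_word_corpus <- function(n_utterances, n_classes = 30L, seed = 0L,
                             n_speakers = 24L) {
  stopifnot(n_classes >= 2, n_utterances >= n_classes)
  templates <- word_class_templates(n_classes, seed)
  withr::with_seed(as.integer(seed) + 1L, {
    base <- n_utterances %/% n_classes
    counts <- rep(base, n_classes)
    extra <- n_utterances - base * n_classes
    if (extra > 0) counts[seq_len(extra)] <- counts[seq_len(extra)] + 1L
    labels <- sample(rep(seq_len(n_classes) - 1L, counts))
    split <- assign_splits(n_utterances)
    male <- stats::runif(n_speakers) < 0.5
    pool_f0 <- ifelse(male, pmax(60, stats::rnorm(n_speakers, 120, 15)),
                      pmax(60, stats::rnorm(n_speakers, 210, 20)))
    pool_vtl <- pmax(0.5, stats::rnorm(n_speakers, ifelse(male, 1.00, 1.18), 0.04))
    spk <- sample.int(n_speakers, n_utterances, replace = TRUE)
    utt_seeds <- sample.int(.Machine$integer.max - 1L, n_utterances)
    waves <- vector("list", n_utterances)
    for (i in seq_len(n_utterances)) {
      prof <- speaker_profile(pool_f0[spk[i]], pool_vtl[spk[i]],
                              jitter_sd = 0.02)
      waves[[i]] <- synthesize_utterance(prof, templates[[labels[i] + 1L]],
                                         utt_seeds[i])
    }
    new_corpus(waves, labels, split, SAMPLE_RATE, as.integer(seed), "words")
  })
}
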