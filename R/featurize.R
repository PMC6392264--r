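#' Featurization configuration
#'
#' Defaults follow the simulation's spectrographic front end: 50 ms Hann
#' windows strided by 10 ms, mel-spaced triangular filters covering
#' 200-7,000 Hz (the range delivered by most cochlear implants), 32 channels
#' for the high-resolution condition and 16 for the medium/low conditions,
#' and linear (raw) amplitude values with no log compression.
#'
#' @param window_ms Analysis window length in ms.
#' @param hop_ms Hop (stride) between windows in ms.
#' @param fmin_hz,fmax_hz Filterbank frequency range in Hz.
#' @param n_channels_high,n_channels_med Channel counts for the high- and
#'   medium-resolution featurizations.
#' @param sample_rate Sampling rate in Hz.
#' @param fft_length FFT length in samples; default is the next power of two
#'   at or above the window length.
#' @param log_amplitude Apply `log1p` compression (off by default; the
#'   pipeline uses raw amplitude spectrograms).
#' @return A `feat_config` list.
#' @export
feat_config <- function(window_ms = 50, hop_ms = 10, fmin_hz = 200,
                        fmax_hz = 7000, n_channels_high = 32L,
                        n_channels_med = 16L, sample_rate = 16000L,
                        fft_length = NULL, log_amplitude = FALSE) {
  stopifnot(window_ms > hop_ms, hop_ms > 0, fmin_hz > 0, fmax_hz > fmin_hz)
  if (fmax_hz > sample_rate / 2) stop("fmax_hz exceeds the Nyquist frequency")
  win <- round(window_ms / 1000 * sample_rate)
  if (is.null(fft_length)) fft_length <- 2^ceiling(log2(win))
  structure(list(window_ms = window_ms, hop_ms = hop_ms, fmin_hz = fmin_hz,
                 fmax_hz = fmax_hz, n_channels_high = as.integer(n_channels_high),
                 n_channels_med = as.integer(n_channels_med),
                 sample_rate = as.integer(sample_rate),
                 fft_length = as.integer(fft_length),
                 log_amplitude = isTRUE(log_amplitude)),
            class = "feat_config")
}

# HTK-style mel scale
hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

#' Mel triangular filterbank
#'
#' Filter centers are equally spaced on the mel scale between `fmin_hz` and
#' `fmax_hz`; each filter is triangular with its feet at the neighboring
#' centers (band edges at the range limits).
#'
#' @param n_channels Number of filters (>= 2).
#' @param config A [feat_config()].
#' @return Matrix `n_channels x (fft_length/2 + 1)` of filter weights, with
#'   attribute `centers_hz`.
#' @export
mel_filterbank <- function(n_channels, config = feat_config()) {
  stopifnot(n_channels >= 2)
  if (config$fmax_hz > config$sample_rate / 2) {
    stop("fmax_hz exceeds the Nyquist frequency")
  }
  n_bins <- config$fft_length %/% 2L + 1L
  bin_hz <- (seq_len(n_bins) - 1) * config$sample_rate / config$fft_length
  pts <- mel_to_hz(seq(hz_to_mel(config$fmin_hz), hz_to_mel(config$fmax_hz),
                       length.out = n_channels + 2L))
  fb <- matrix(0, nrow = n_channels, ncol = n_bins)
  for (k in seq_len(n_channels)) {
    lo <- pts[k]; ce <- pts[k + 1L]; hi <- pts[k + 2L]
    up <- (bin_hz - lo) / (ce - lo)
    down <- (hi - bin_hz) / (hi - ce)
    fb[k, ] <- pmax(0, pmin(up, down))
  }
  attr(fb, "centers_hz") <- pts[2:(n_channels + 1L)]
  fb
}

new_spectrogram <- function(values, centers, times, tag, duplicated = FALSE) {
  structure(list(values = values, channel_centers_hz = centers,
                 frame_times_s = times, resolution_tag = tag,
                 duplicated = duplicated),
            class = "ci_spectrogram")
}

#' @export
print.ci_spectrogram <- function(x, ...) {
  cat(sprintf("<ci_spectrogram> %d x %d (%s%s)\n", nrow(x$values),
              ncol(x$values), x$resolution_tag,
              if (x$duplicated) ", row-duplicated" else ""))
  invisible(x)
}

#' Mel amplitude spectrogram of a waveform
#'
#' Short-time magnitude spectra (Hann window) passed through the mel
#' filterbank. No log compression is applied unless configured: the values
#' are raw linear amplitudes.
#'
#' @param waveform Numeric vector at `config$sample_rate`.
#' @param n_channels Number of mel channels.
#' @param config A [feat_config()].
#' @param resolution_tag Tag stored on the result.
#' @return A `ci_spectrogram` with an `n_channels x T` non-negative matrix,
#'   where `T = floor((length - window) / hop) + 1`.
#' @export
compute_spectrogram <- function(waveform, n_channels, config = feat_config(),
                                resolution_tag = "high") {
  win <- round(config$window_ms / 1000 * config$sample_rate)
  hop <- round(config$hop_ms / 1000 * config$sample_rate)
  if (length(waveform) < win) {
    stop(sprintf("waveform has %d samples; at least one window (%d) required",
                 length(waveform), win))
  }
  n_frames <- (length(waveform) - win) %/% hop + 1L
  idx <- outer(seq_len(win), (seq_len(n_frames) - 1L) * hop, "+")
  frames <- matrix(waveform[idx], nrow = win)
  hann <- 0.5 - 0.5 * cos(2 * pi * (seq_len(win) - 1) / win)
  frames <- frames * hann
  if (config$fft_length > win) {
    frames <- rbind(frames, matrix(0, config$fft_length - win, n_frames))
  }
  spec <- Mod(stats::mvfft(frames))[seq_len(config$fft_length %/% 2L + 1L), ,
                                    drop = FALSE]
  fb <- mel_filterbank(n_channels, config)
  vals <- fb %*% spec
  if (config$log_amplitude) vals <- log1p(vals)
  times <- ((seq_len(n_frames) - 1L) * hop + win / 2) / config$sample_rate
  new_spectrogram(vals, attr(fb, "centers_hz"), times, resolution_tag)
}

# the fixed neighbor-summation operator as a matrix: tridiagonal ones
channel_interaction_matrix <- function(n) {
  stopifnot(n >= 2)
  m <- diag(n)
  m[cbind(seq_len(n - 1), seq_len(n - 1) + 1L)] <- 1
  m[cbind(seq_len(n - 1) + 1L, seq_len(n - 1))] <- 1
  m
}

#' Channel interaction: sum each channel with its neighbors
#'
#' Models the summation of electrical fields from neighboring cochlear-implant
#' electrodes by linearly combining adjacent spectrogram rows: edge rows are
#' summed with their single neighbor, inner rows with both neighbors. All rows
#' are computed from the original matrix simultaneously (no in-place
#' cascading); the operator equals left-multiplication by the tridiagonal
#' ones matrix.
#'
#' @param x A `ci_spectrogram` (medium resolution, un-duplicated) or a plain
#'   matrix with >= 2 rows.
#' @return Same type as the input, with combined rows; spectrogram results
#'   are tagged `"low"`.
#' @export
apply_channel_interaction <- function(x) {
  if (inherits(x, "ci_spectrogram")) {
    if (x$duplicated) stop("channel interaction applies before row duplication")
    if (x$resolution_tag != "med") {
      stop("channel interaction applies to the medium-resolution spectrogram")
    }
    x$values <- apply_channel_interaction(x$values)
    x$resolution_tag <- "low"
    return(x)
  }
  stopifnot(is.matrix(x))
  n <- nrow(x)
  if (n < 2L) stop("at least 2 channels required for channel interaction")
  up <- rbind(x[-1, , drop = FALSE], 0)      # x[n+1, ]
  down <- rbind(0, x[-n, , drop = FALSE])    # x[n-1, ]
  x + up + down
}

#' Duplicate spectrogram rows
#'
#' Presents 16-channel spectrograms as 32 x T matrices by repeating each row
#' (rows 2k-1 and 2k both equal input row k), so one network can ingest all
#' three resolutions.
#'
#' @param x A 16-row `ci_spectrogram`, or a plain matrix.
#' @return Input with each row duplicated; channel centers repeated pairwise.
#' @export
duplicate_rows <- function(x) {
  if (inherits(x, "ci_spectrogram")) {
    if (x$duplicated || nrow(x$values) != 16L) {
      stop("row duplication applies once, to a 16-channel spectrogram")
    }
    x$values <- duplicate_rows(x$values)
    x$channel_centers_hz <- rep(x$channel_centers_hz, each = 2L)
    x$duplicated <- TRUE
    return(x)
  }
  stopifnot(is.matrix(x))
  x[rep(seq_len(nrow(x)), each = 2L), , drop = FALSE]
}

#' Featurize a waveform at one of the three resolutions
#'
#' * `high`: 32-channel mel spectrogram (intact-cochlea approximation).
#' * `med`: 16 channels, rows duplicated (implant without channel interaction).
#' * `low`: 16 channels with neighbor summation, then rows duplicated
#'   (realistic implant).
#'
#' All three emit a 32 x T matrix.
#'
#' @param waveform Numeric vector at the configured sampling rate.
#' @param resolution One of `"high"`, `"med"`, `"low"`.
#' @param config A [feat_config()].
#' @return A 32-row `ci_spectrogram`.
#' @export
featurize <- function(waveform, resolution = c("high", "med", "low"),
                      config = feat_config()) {
  resolution <- match.arg(resolution)
  if (resolution == "high") {
    return(compute_spectrogram(waveform, config$n_channels_high, config, "high"))
  }
  s <- compute_spectrogram(waveform, config$n_channels_med, config, "med")
  if (resolution == "low") s <- apply_channel_interaction(s)
  duplicate_rows(s)
}

#' Flatten a spectrogram row-major by channel
#'
#' Concatenates the rows (frequency bands) of an `N x T` spectrogram into a
#' length-`NT` vector: element `(n-1)*T + t` equals `x[n, t]`.
#'
#' @param spec A `ci_spectrogram` or matrix.
#' @return Numeric vector of length `N * T`.
#' @export
vectorize <- function(spec) {
  m <- if (inherits(spec, "ci_spectrogram")) spec$values else spec
  as.vector(t(m))
}

# pad with zero frames / truncate to a fixed frame count
fit_frames <- function(values, n_frames) {
  t_in <- ncol(values)
  if (t_in >= n_frames) return(values[, seq_len(n_frames), drop = FALSE])
  cbind(values, matrix(0, nrow(values), n_frames - t_in))
}

#' Featurize a whole corpus into a fixed-size array
#'
#' Computes one spectrogram per utterance and pads with zero frames (or
#' truncates) to a common frame count so the matrices can feed fixed-input
#' models. For variable-duration corpora the default frame count is the 95th
#' percentile of the observed frame counts; for fixed 1 s utterances it is
#' the natural 96.
#'
#' @param corpus A `ci_corpus`.
#' @param resolution One of `"high"`, `"med"`, `"low"`.
#' @param config A [feat_config()].
#' @param n_frames Fixed frame count; `NULL` picks the default above.
#' @param normalize Standardize each feature (channel x frame cell) to zero
#'   mean and unit variance using train-split statistics (default `TRUE`).
#'   This is a model-input conditioning step: the spectrograms themselves
#'   remain raw non-negative amplitudes.
#' @return A `ci_features` list: `x` (array `n x 32 x n_frames`), `y`
#'   (integer labels, 0-based), `split`, `n_classes`, `resolution`.
#' @export
featurize_corpus <- function(corpus, resolution = c("high", "med", "low"),
                             config = feat_config(), n_frames = NULL,
                             normalize = TRUE) {
  resolution <- match.arg(resolution)
  stopifnot(inherits(corpus, "ci_corpus"))
  specs <- lapply(corpus$waveforms, featurize, resolution = resolution,
                  config = config)
  t_all <- vapply(specs, function(s) ncol(s$values), integer(1))
  if (is.null(n_frames)) {
    n_frames <- if (length(unique(t_all)) == 1L) t_all[1] else
      as.integer(round(stats::quantile(t_all, 0.95, type = 1)))
  }
  n <- length(specs)
  x <- array(0, dim = c(n, nrow(specs[[1]]$values), n_frames))
  for (i in seq_len(n)) x[i, , ] <- fit_frames(specs[[i]]$values, n_frames)
  if (isTRUE(normalize)) {
    tr <- corpus$split == "train"
    if (!any(tr)) tr <- rep(TRUE, n)
    mu <- apply(x[tr, , , drop = FALSE], c(2, 3), mean)
    sig <- apply(x[tr, , , drop = FALSE], c(2, 3), stats::sd)
    sig[!is.finite(sig) | sig < 1e-8] <- 1
    for (i in seq_len(n)) x[i, , ] <- (x[i, , ] - mu) / sig
  }
  structure(list(x = x, y = corpus$labels, split = corpus$split,
                 n_classes = length(unique(corpus$labels)),
                 resolution = resolution, n_frames = as.integer(n_frames),
                 normalized = isTRUE(normalize), config = config),
            class = "ci_features")
}

# flatten a ci_features array into an n x (32*T) design matrix using the
# row-major-by-channel vectorization convention
flatten_features <- function(feats, rows = NULL) {
  x <- feats$x
  if (!is.null(rows)) x <- x[rows, , , drop = FALSE]
  d <- dim(x)
  matrix(aperm(x, c(3, 2, 1)), nrow = d[1], byrow = TRUE)
}

# subset a ci_features by split name
feature_split <- function(feats, which) {
  rows <- feats$split == which
  list(x = feats$x[rows, , , drop = FALSE], y = feats$y[rows],
       xmat = flatten_features(feats, rows))
}
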