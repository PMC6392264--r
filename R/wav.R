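#' Write a mono waveform as a 16-bit PCM WAV file
#'
#' Writes a standard RIFF/WAVE file (PCM, 16-bit, single channel). Samples are
#' clipped to `[-1, 1]` and scaled to the signed 16-bit range.
#'
#' @param x Numeric vector of samples in `[-1, 1]`.
#' @param path Output file path.
#' @param sample_rate Sampling rate in Hz.
#' @return `path`, invisibly.
#' @export
write_wav <- function(x, path, sample_rate = 16000L) {
  stopifnot(is.numeric(x), length(x) >= 1L, all(is.finite(x)))
  x <- pmax(pmin(x, 1), -1)
  pcm <- as.integer(round(x * 32767))
  n <- length(pcm)
  data_bytes <- n * 2L
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")           # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")            # PCM
  writeBin(1L, con, size = 2, endian = "little")            # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate) * 2L, con, size = 4, endian = "little")  # byte rate
  writeBin(2L, con, size = 2, endian = "little")            # block align
  writeBin(16L, con, size = 2, endian = "little")           # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM mono WAV file
#'
#' Parses RIFF chunks and returns samples rescaled to `[-1, 1]`. Only
#' uncompressed 16-bit single-channel files are supported.
#'
#' @param path Path to a WAV file.
#' @return List with `samples` (numeric vector) and `sample_rate` (integer).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  readBin(con, integer(), size = 4, endian = "little")
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  sample_rate <- NULL
  samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, integer(), size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, integer(), n = 2, size = 2, endian = "little")
      if (fmt[1] != 1L) stop("unsupported WAV encoding (not PCM): ", path)
      if (fmt[2] != 1L) stop("only mono WAV is supported: ", path)
      sample_rate <- readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 4, endian = "little")
      block <- readBin(con, integer(), size = 2, endian = "little")
      bits <- readBin(con, integer(), size = 2, endian = "little")
      if (bits != 16L) stop("only 16-bit PCM is supported: ", path)
      extra <- size - 16L
      if (extra > 0L) readBin(con, raw(), n = extra)
      invisible(block)
    } else if (identical(id, "data")) {
      samples <- readBin(con, integer(), n = size %/% 2L, size = 2,
                         signed = TRUE, endian = "little")
    } else {
      readBin(con, raw(), n = size + (size %% 2L))
    }
    if (!is.null(sample_rate) && !is.null(samples)) break
  }
  if (is.null(samples)) stop("no data chunk found in ", path)
  list(samples = samples / 32767, sample_rate = as.integer(sample_rate))
}

#' Write a corpus to a directory of WAV files plus a manifest
#'
#' One 16-bit PCM WAV per utterance and a `manifest.csv` with columns
#' `filename,label,split`.
#'
#' @param corpus A `ci_corpus` (see [make_gender_corpus()]).
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  stopifnot(inherits(corpus, "ci_corpus"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(corpus$waveforms)
  fn <- sprintf("utt_%05d.wav", seq_len(n))
  for (i in seq_len(n)) {
    write_wav(corpus$waveforms[[i]], file.path(dir, fn[i]),
              sample_rate = corpus$sample_rate)
  }
  manifest <- data.frame(filename = fn, label = corpus$labels,
                         split = corpus$split, stringsAsFactors = FALSE)
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a labelled corpus from a directory of WAV files with a manifest
#'
#' The directory must contain mono 16 kHz WAV files and a `manifest.csv` with
#' columns `filename,label,split`. This is the entry point for user-supplied
#' real speech data.
#'
#' @param dir Directory path.
#' @return A `ci_corpus`.
#' @export
read_corpus <- function(dir) {
  path <- file.path(dir, "manifest.csv")
  if (!file.exists(path)) stop("no manifest.csv in ", dir)
  manifest <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("filename", "label", "split")
  if (!all(required %in% names(manifest))) {
    stop("manifest must have columns: ", paste(required, collapse = ", "))
  }
  waves <- vector("list", nrow(manifest))
  sr <- NULL
  for (i in seq_len(nrow(manifest))) {
    w <- read_wav(file.path(dir, manifest$filename[i]))
    if (is.null(sr)) sr <- w$sample_rate
    if (w$sample_rate != sr) stop("inconsistent sample rates in ", dir)
    waves[[i]] <- w$samples
  }
  new_corpus(waveforms = waves, labels = as.integer(manifest$label),
             split = manifest$split, sample_rate = sr, seed = NA_integer_)
}
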