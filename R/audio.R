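#' Construct an audio signal
#'
#' The basic unit of all audio I/O and signal processing in vocsim: a mono
#' sample vector together with its sampling rate in Hz.
#'
#' @param samples Numeric vector of samples (mono).
#' @param fs Sampling rate in Hz (positive scalar).
#' @return An object of class `audio_signal` with fields `samples` and `fs`.
#' @examples
#' x <- audio_signal(sin(2 * pi * 440 * seq(0, 1, by = 1 / 16000)), 16000)
#' duration(x)
#' @export
audio_signal <- function(samples, fs) {
  if (!is.numeric(samples)) {
    stop("`samples` must be numeric", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1 || !is.finite(fs) || fs <= 0) {
    stop("`fs` must be a positive scalar (Hz)", call. = FALSE)
  }
  structure(
    list(samples = as.numeric(samples), fs = as.numeric(fs)),
    class = "audio_signal"
  )
}

#' @export
print.audio_signal <- function(x, ...) {
  cat(sprintf(
    "<audio_signal: %d samples @ %g Hz (%.3f s), RMS %.4g>\n",
    length(x$samples), x$fs, duration(x), rms(x)
  ))
  invisible(x)
}

#' @export
length.audio_signal <- function(x) length(x$samples)

#' Duration of an audio signal in seconds
#' @param x An `audio_signal`.
#' @return Duration in seconds.
#' @export
duration <- function(x) {
  stopifnot(inherits(x, "audio_signal"))
  length(x$samples) / x$fs
}

#' Root-mean-square amplitude
#' @param x An `audio_signal` or numeric vector.
#' @return RMS amplitude (linear units).
#' @export
rms <- function(x) {
  v <- if (inherits(x, "audio_signal")) x$samples else x
  sqrt(mean(v^2))
}

as_samples <- function(x) {
  if (inherits(x, "audio_signal")) x$samples else as.numeric(x)
}

#' Read a mono WAV file
#'
#' Reads RIFF/WAVE files containing 16-bit PCM or 32-bit IEEE float samples.
#' Multi-channel files are refused: the vocoder chain is mono end to end.
#'
#' @param path Path to a `.wav` file.
#' @return An [audio_signal()]. PCM samples are scaled to `[-1, 1)`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path, call. = FALSE)
  readBin(con, "integer", 1, size = 4, endian = "little")
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path, call. = FALSE)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- list(
        audio_format = readBin(con, "integer", 1, size = 2, endian = "little", signed = FALSE),
        n_channels   = readBin(con, "integer", 1, size = 2, endian = "little", signed = FALSE),
        sample_rate  = readBin(con, "integer", 1, size = 4, endian = "little"),
        byte_rate    = readBin(con, "integer", 1, size = 4, endian = "little"),
        block_align  = readBin(con, "integer", 1, size = 2, endian = "little", signed = FALSE),
        bits         = readBin(con, "integer", 1, size = 2, endian = "little", signed = FALSE)
      )
      if (sz > 16) readBin(con, "raw", sz - 16)
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
      if (sz %% 2 == 1) readBin(con, "raw", 1) # chunk padding
    } else {
      readBin(con, "raw", sz + sz %% 2)
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) {
    stop("missing fmt/data chunk in ", path, call. = FALSE)
  }
  if (fmt$n_channels != 1) {
    stop("only mono WAV supported (file has ", fmt$n_channels, " channels)", call. = FALSE)
  }
  samples <- switch(
    as.character(fmt$audio_format),
    "1" = {
      if (fmt$bits != 16) stop("only 16-bit PCM supported", call. = FALSE)
      readBin(data_raw, "integer", length(data_raw) / 2, size = 2,
              endian = "little", signed = TRUE) / 32768
    },
    "3" = {
      if (fmt$bits != 32) stop("only 32-bit float supported", call. = FALSE)
      readBin(data_raw, "double", length(data_raw) / 4, size = 4, endian = "little")
    },
    stop("unsupported WAV format code ", fmt$audio_format, call. = FALSE)
  )
  audio_signal(samples, fmt$sample_rate)
}

#' Write a mono WAV file
#'
#' @param x An [audio_signal()].
#' @param path Output path.
#' @param format `"float32"` (default; lossless for pipeline output) or
#'   `"pcm16"`. PCM output clips to `[-1, 1)`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(x, path, format = c("float32", "pcm16")) {
  stopifnot(inherits(x, "audio_signal"))
  format <- match.arg(format)
  n <- length(x$samples)
  bytes_per <- if (format == "pcm16") 2L else 4L
  data_size <- n * bytes_per

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(if (format == "pcm16") 1L else 3L, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")
  writeBin(as.integer(round(x$fs)), con, size = 4, endian = "little")
  writeBin(as.integer(round(x$fs) * bytes_per), con, size = 4, endian = "little")
  writeBin(bytes_per, con, size = 2, endian = "little")
  writeBin(8L * bytes_per, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (format == "pcm16") {
    s <- pmax(pmin(x$samples, 32767 / 32768), -1)
    writeBin(as.integer(round(s * 32768)), con, size = 2, endian = "little")
  } else {
    writeBin(x$samples, con, size = 4, endian = "little")
  }
  invisible(path)
}
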