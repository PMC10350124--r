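#' Long-term average spectrum target
#'
#' A target spectrum for speech-shaped noise generation, as relative dB levels
#' on an increasing frequency grid.
#'
#' @param frequencies Increasing frequency grid in Hz.
#' @param levels_db Finite relative levels in dB.
#' @return An object of class `spectrum_target`.
#' @export
spectrum_target <- function(frequencies, levels_db) {
  if (length(frequencies) != length(levels_db) || length(frequencies) < 2) {
    stop("need matching frequency/level vectors of length >= 2", call. = FALSE)
  }
  if (any(diff(frequencies) <= 0)) {
    stop("frequencies must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(levels_db))) stop("levels must be finite", call. = FALSE)
  structure(list(frequencies = as.numeric(frequencies),
                 levels_db = as.numeric(levels_db)),
            class = "spectrum_target")
}

# Welch-averaged one-sided amplitude spectrum (Hann window, 50% overlap)
welch_spectrum <- function(x, fs, nfft = 1024) {
  x <- as_samples(x)
  if (length(x) < nfft) {
    x <- c(x, numeric(nfft - length(x)))
  }
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nfft) / nfft)
  hop <- nfft %/% 2
  starts <- seq(1, length(x) - nfft + 1, by = hop)
  acc <- numeric(nfft %/% 2 + 1)
  for (s in starts) {
    seg <- x[s:(s + nfft - 1)] * w
    p <- abs(stats::fft(seg))^2
    acc <- acc + p[seq_len(nfft %/% 2 + 1)]
  }
  acc <- acc / length(starts)
  list(frequencies = (0:(nfft %/% 2)) * fs / nfft,
       amplitude = sqrt(acc))
}

#' Long-term average spectrum in third-octave bands
#'
#' Average band level (dB) of a signal in third-octave bands, used to compare
#' generated noise against a reference spectrum shape.
#'
#' @param x An [audio_signal()].
#' @param f_range Frequency range covered by the band centers, in Hz.
#' @param nfft Welch segment length.
#' @return A tibble with columns `f_center` (Hz) and `level_db`.
#' @export
third_octave_ltas <- function(x, f_range = c(200, 7000), nfft = 1024) {
  stopifnot(inherits(x, "audio_signal"))
  sp <- welch_spectrum(x$samples, x$fs, nfft)
  centers <- c()
  f <- f_range[1]
  while (f <= f_range[2]) {
    centers <- c(centers, f)
    f <- f * 2^(1 / 3)
  }
  lev <- vapply(centers, function(fc) {
    lo <- fc / 2^(1 / 6)
    hi <- fc * 2^(1 / 6)
    sel <- sp$frequencies >= lo & sp$frequencies < hi
    10 * log10(mean(sp$amplitude[sel]^2))
  }, numeric(1))
  tibble::tibble(f_center = centers, level_db = lev)
}

#' Generate speech-shaped noise
#'
#' Filters seeded white noise so its long-term average spectrum matches a
#' reference: either one or more speech recordings (their Welch-averaged
#' spectrum becomes the target) or an explicit [spectrum_target()]. The
#' shaping filter is a linear-phase FIR designed by frequency sampling.
#' Output RMS is normalized to 1; scale it with [mix_at_snr()].
#'
#' @param reference An [audio_signal()], a list of them, or a
#'   [spectrum_target()].
#' @param duration Output duration in seconds (> 0).
#' @param fs Output sample rate in Hz; reference audio must share it.
#' @param seed Integer RNG seed; fixed seed gives identical samples.
#' @param fir_taps Length of the shaping FIR (default 512).
#' @param nfft Welch segment length for reference spectrum estimation.
#' @return An [audio_signal()] of exactly `round(duration * fs)` samples.
#' @export
speech_shaped_noise <- function(reference, duration, fs, seed = 1L,
                                fir_taps = 512, nfft = 1024) {
  if (duration <= 0) stop("`duration` must be > 0", call. = FALSE)
  if (inherits(reference, "audio_signal")) reference <- list(reference)
  nyq <- fs / 2

  if (inherits(reference, "spectrum_target")) {
    grid_f <- reference$frequencies
    grid_a <- 10^(reference$levels_db / 20)
  } else {
    if (!is.list(reference) || length(reference) == 0) {
      stop("`reference` must be audio, a list of audio, or a spectrum_target",
           call. = FALSE)
    }
    for (r in reference) {
      stopifnot(inherits(r, "audio_signal"))
      if (r$fs != fs) {
        stop("reference audio sample rate (", r$fs, ") != requested fs (", fs,
             ")", call. = FALSE)
      }
    }
    cat_samples <- unlist(lapply(reference, function(r) r$samples))
    sp <- welch_spectrum(cat_samples, fs, nfft)
    grid_f <- sp$frequencies
    grid_a <- sp$amplitude
  }

  # frequency-sampling FIR over the normalized 0..1 (Nyquist) grid
  f_norm <- pmin(grid_f / nyq, 1)
  keep <- f_norm <= 1
  f_norm <- f_norm[keep]
  grid_a <- grid_a[keep]
  if (f_norm[1] > 0) {
    f_norm <- c(0, f_norm)
    grid_a <- c(grid_a[1], grid_a)
  }
  if (f_norm[length(f_norm)] < 1) {
    f_norm <- c(f_norm, 1)
    grid_a <- c(grid_a, grid_a[length(grid_a)])
  }
  grid_a <- grid_a / max(grid_a)
  fir <- as.numeric(signal::fir2(fir_taps, f_norm, grid_a))

  n <- round(duration * fs)
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  white <- stats::rnorm(n + fir_taps)
  shaped <- as.numeric(signal::filter(fir, 1, white))
  out <- shaped[(fir_taps + 1):(fir_taps + n)]
  audio_signal(out / sqrt(mean(out^2)), fs)
}

#' Mix speech and noise at a target SNR
#'
#' Scales the noise so that `20 log10(rms(speech) / rms(noise))` equals the
#' requested SNR, then adds it to the speech. RMS is computed over the full
#' extent of each file. `snr_db = "quiet"` returns the speech unchanged.
#'
#' @param speech,noise [audio_signal()]s at the same sample rate; noise at
#'   least as long as speech (excess is trimmed).
#' @param snr_db Signal-to-noise ratio in dB, or `"quiet"`.
#' @return The mixture as an [audio_signal()].
#' @examples
#' s <- audio_signal(sin(2 * pi * 440 * (0:15999) / 16000), 16000)
#' n <- audio_signal(stats::rnorm(16000), 16000)
#' m <- mix_at_snr(s, n, 5)
#' @export
mix_at_snr <- function(speech, noise, snr_db) {
  stopifnot(inherits(speech, "audio_signal"))
  if (identical(snr_db, "quiet")) {
    return(speech)
  }
  stopifnot(inherits(noise, "audio_signal"))
  if (speech$fs != noise$fs) {
    stop("sample-rate mismatch: speech ", speech$fs, " Hz vs noise ",
         noise$fs, " Hz", call. = FALSE)
  }
  if (length(noise$samples) < length(speech$samples)) {
    stop("noise shorter than speech", call. = FALSE)
  }
  snr_db <- as.numeric(snr_db)
  nn <- noise$samples[seq_along(speech$samples)]
  scale <- rms(speech$samples) / rms(nn) * 10^(-snr_db / 20)
  audio_signal(speech$samples + scale * nn, speech$fs)
}
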