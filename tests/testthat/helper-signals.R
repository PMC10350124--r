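# Shared fixtures: simple deterministic test signals and measures.

FS <- 16000

pure_tone <- function(freq, dur = 1, fs = FS, amp = 1) {
  t <- (seq_len(round(dur * fs)) - 1) / fs
  audio_signal(amp * sin(2 * pi * freq * t), fs)
}

# Correlation at the best lag within `max_lag_s`, compensating the constant
# group delay of the causal envelope filter.
lag_corr <- function(x, y, fs = FS, max_lag_s = 0.025, discard_s = 0.1) {
  keep <- (round(discard_s * fs) + round(max_lag_s * fs) + 1):length(x)
  lags <- 0:round(max_lag_s * fs)
  max(vapply(lags, function(l) stats::cor(x[keep], y[keep - l]), numeric(1)))
}

# Fraction of periodogram energy inside [lo, hi] Hz
band_energy_fraction <- function(x, lo, hi) {
  sp <- stats::spec.pgram(x$samples, taper = 0, plot = FALSE, fast = TRUE)
  f <- sp$freq * x$fs
  sum(sp$spec[f >= lo & f <= hi]) / sum(sp$spec)
}

# Fixed synthetic speech-like long-term spectrum target
speechlike_target <- function() {
  spectrum_target(c(0, 100, 300, 500, 1000, 2000, 4000, 8000),
                  c(-20, 0, 5, 3, 0, -8, -16, -30))
}

# Tiny stimulus set for experiment tests: two AM complexes with scripted text
tiny_stimuli <- function(dur = 0.5) {
  tibble::tibble(
    id = c("s1", "s2"),
    audio = list(
      synth_stimulus(f0 = 150, n_harmonics = 8, am_rate = 4, dur = dur, seed = 1)$audio,
      synth_stimulus(f0 = 220, n_harmonics = 6, am_rate = 6, dur = dur, seed = 2)$audio
    ),
    transcript = c("the boy ran home", "a dog sat down")
  )
}
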