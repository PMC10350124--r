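#' Envelope matrix
#'
#' N x T matrix of non-negative channel envelope amplitudes (one row per
#' vocoder channel) plus the sample rate. All envelope degradations act on
#' this object.
#'
#' @param values Numeric N x T matrix, all values >= 0.
#' @param fs Sample rate in Hz.
#' @return An object of class `envelope_matrix`.
#' @export
envelope_matrix <- function(values, fs) {
  values <- as.matrix(values)
  if (length(values) == 0) stop("empty envelope", call. = FALSE)
  if (any(values < 0)) stop("envelope values must be >= 0", call. = FALSE)
  structure(list(values = values, fs = as.numeric(fs)), class = "envelope_matrix")
}

#' @export
print.envelope_matrix <- function(x, ...) {
  cat(sprintf("<envelope_matrix: %d channels x %d samples @ %g Hz, max %.4g>\n",
              nrow(x$values), ncol(x$values), x$fs, max(x$values)))
  invisible(x)
}

#' @export
dim.envelope_matrix <- function(x) dim(x$values)

#' Vocoder parameter record
#'
#' Bundles the five manipulated vocoder parameters plus carrier seed and
#' filter orders. Defaults are the standard operating point: 8 equal-octave
#' channels over 200-7900 Hz, 100 Hz envelope cutoff, full dynamic range,
#' continuous (unquantized) envelopes.
#'
#' @param n_channels Number of channels. In `paper_mode` restricted to
#'   {4, 6, 8, 10, 12, 16, 22}; otherwise any count >= 1.
#' @param edge_mode `"equal_octave"` or `"cochlear_standard"`.
#' @param f_low,f_high Overall frequency range in Hz (equal-octave mode).
#' @param env_cutoff Envelope low-pass corner frequency in Hz.
#' @param dynamic_range_db Envelope dynamic range in dB, or `"full"` for no
#'   limiting.
#' @param quant_steps Number of quantized envelope levels, or `"infinite"`
#'   for continuous envelopes.
#' @param carrier_seed Integer seed for the noise carriers.
#' @param filter_spec A [filter_spec()].
#' @param paper_mode Enforce the study's channel-count set.
#' @return An object of class `vocoder_params`.
#' @export
vocoder_params <- function(n_channels = 8L,
                           edge_mode = c("equal_octave", "cochlear_standard"),
                           f_low = 200, f_high = 7900,
                           env_cutoff = 100,
                           dynamic_range_db = "full",
                           quant_steps = "infinite",
                           carrier_seed = 1L,
                           filter_spec = vocsim::filter_spec(),
                           paper_mode = TRUE) {
  edge_mode <- match.arg(edge_mode)
  n_channels <- as.integer(n_channels)
  if (n_channels < 1) stop("`n_channels` must be >= 1", call. = FALSE)
  if (paper_mode && !n_channels %in% c(4L, 6L, 8L, 10L, 12L, 16L, 22L)) {
    stop("`n_channels` must be one of 4, 6, 8, 10, 12, 16, 22 ",
         "(set paper_mode = FALSE to lift)", call. = FALSE)
  }
  if (!identical(dynamic_range_db, "full")) {
    dynamic_range_db <- as.numeric(dynamic_range_db)
    if (!is.finite(dynamic_range_db) || dynamic_range_db <= 0) {
      stop("`dynamic_range_db` must be > 0 or \"full\"", call. = FALSE)
    }
  }
  if (!identical(quant_steps, "infinite")) {
    quant_steps <- as.integer(quant_steps)
    if (is.na(quant_steps) || quant_steps < 1) {
      stop("`quant_steps` must be >= 1 or \"infinite\"", call. = FALSE)
    }
  }
  if (!is.numeric(env_cutoff) || env_cutoff <= 0) {
    stop("`env_cutoff` must be > 0", call. = FALSE)
  }
  structure(
    list(n_channels = n_channels, edge_mode = edge_mode,
         f_low = f_low, f_high = f_high, env_cutoff = env_cutoff,
         dynamic_range_db = dynamic_range_db, quant_steps = quant_steps,
         carrier_seed = as.integer(carrier_seed), filter_spec = filter_spec),
    class = "vocoder_params"
  )
}

#' @export
print.vocoder_params <- function(x, ...) {
  dr <- if (identical(x$dynamic_range_db, "full")) "full" else paste0(x$dynamic_range_db, " dB")
  qs <- if (identical(x$quant_steps, "infinite")) "infinite" else x$quant_steps
  cat(sprintf(paste0(
    "<vocoder_params: %d channels (%s), %g-%g Hz, env cutoff %g Hz, ",
    "dynamic range %s, steps %s, seed %d>\n"),
    x$n_channels, x$edge_mode, x$f_low, x$f_high, x$env_cutoff, dr, qs,
    x$carrier_seed))
  invisible(x)
}

edges_for <- function(params) {
  switch(params$edge_mode,
    equal_octave = equal_octave_edges(params$f_low, params$f_high, params$n_channels),
    cochlear_standard = cochlear_edges(params$n_channels)
  )
}

#' Extract channel envelopes
#'
#' Half-wave rectifies each band signal and low-pass filters it with a
#' Butterworth filter at `env_cutoff` (4 poles by default). Residual negative
#' ripple from the low-pass is clamped to zero.
#'
#' @param channels List of band-limited [audio_signal()]s from [split_bands()].
#' @param env_cutoff Envelope low-pass corner frequency in Hz.
#' @param spec A [filter_spec()]; `lowpass_order` is used.
#' @return An [envelope_matrix()] with one row per channel.
#' @export
extract_envelopes <- function(channels, env_cutoff = 100, spec = filter_spec()) {
  if (length(channels) == 0) stop("no channels", call. = FALSE)
  fs <- channels[[1]]$fs
  if (env_cutoff >= fs / 2) {
    stop("`env_cutoff` (", env_cutoff, " Hz) at/above Nyquist", call. = FALSE)
  }
  sos <- butter_lowpass_sos(spec$lowpass_order, env_cutoff, fs)
  rows <- lapply(channels, function(ch) {
    env <- sos_filter(sos, pmax(ch$samples, 0))
    if (spec$zero_phase) env <- rev(sos_filter(sos, rev(env)))
    pmax(env, 0)
  })
  envelope_matrix(do.call(rbind, rows), fs)
}

#' Limit envelope dynamic range
#'
#' Zeroes every envelope value more than `dr_db` decibels below the global
#' envelope maximum. The reference maximum is taken over ALL channels and
#' samples of the stimulus, so a uniformly weak channel can be silenced
#' entirely. Decibels are amplitude dB (20 log10).
#'
#' @param env An [envelope_matrix()].
#' @param dr_db Dynamic range in dB (> 0), or `"full"` for no limiting.
#' @return An [envelope_matrix()] with sub-floor values set to zero.
#' @examples
#' e <- envelope_matrix(matrix(c(1, 0.1, 0.001), 1), 16000)
#' limit_dynamic_range(e, 40)$values # 0.001 is below the 0.01 floor -> 0
#' @export
limit_dynamic_range <- function(env, dr_db = "full") {
  stopifnot(inherits(env, "envelope_matrix"))
  if (identical(dr_db, "full")) {
    return(env)
  }
  dr_db <- as.numeric(dr_db)
  if (!is.finite(dr_db) || dr_db <= 0) {
    stop("`dr_db` must be > 0 or \"full\"", call. = FALSE)
  }
  m <- max(env$values)
  if (m == 0) {
    return(env)
  }
  floor_lin <- m * 10^(-dr_db / 20)
  v <- env$values
  v[v < floor_lin] <- 0
  envelope_matrix(v, env$fs)
}

quant_levels_db <- function(max_db, dr_db, n_steps) {
  if (n_steps == 1) {
    max_db
  } else {
    seq(max_db - dr_db, max_db, length.out = n_steps)
  }
}

#' Quantize envelopes to equal dB steps
#'
#' Rounds every nonzero envelope value to the nearest of `n_steps` levels
#' evenly spaced in dB over the dynamic range `[M_dB - dr_db, M_dB]`, where
#' `M` is the global envelope maximum. Logarithmic (dB) steps model the
#' discriminable loudness steps of an implant listener. Zeros (values already
#' removed by dynamic-range limiting) stay zero. Exact midpoints round toward
#' the louder level. Normally applied after [limit_dynamic_range()] with the
#' same `dr_db`.
#'
#' @param env An [envelope_matrix()].
#' @param n_steps Number of levels (>= 1), or `"infinite"` for no quantization.
#' @param dr_db Dynamic range in dB spanned by the level grid. Required finite
#'   when `n_steps` is finite.
#' @return An [envelope_matrix()] whose nonzero values lie on the level grid.
#' @export
quantize_envelopes <- function(env, n_steps = "infinite", dr_db = NULL) {
  stopifnot(inherits(env, "envelope_matrix"))
  if (identical(n_steps, "infinite")) {
    return(env)
  }
  n_steps <- as.integer(n_steps)
  if (is.na(n_steps) || n_steps < 1) {
    stop("`n_steps` must be >= 1 or \"infinite\"", call. = FALSE)
  }
  if (is.null(dr_db) || identical(dr_db, "full") || !is.finite(as.numeric(dr_db))) {
    stop("quantization needs a finite `dr_db` to define the level grid; ",
         "\"full\" dynamic range has no equal-dB division", call. = FALSE)
  }
  dr_db <- as.numeric(dr_db)
  m <- max(env$values)
  if (m == 0) {
    return(env)
  }
  levels_db <- quant_levels_db(20 * log10(m), dr_db, n_steps)
  v <- env$values
  nz <- v > 0
  vdb <- 20 * log10(v[nz])
  if (n_steps == 1) {
    idx <- rep(1L, length(vdb))
  } else {
    step <- dr_db / (n_steps - 1)
    # nearest level in dB; exact midpoints round up (toward the louder level)
    idx <- floor((vdb - levels_db[1]) / step + 0.5) + 1
    idx <- pmin(pmax(idx, 1), n_steps)
  }
  v[nz] <- 10^(levels_db[idx] / 20)
  envelope_matrix(v, env$fs)
}

#' Synthesize a vocoded waveform from envelopes
#'
#' Per channel: a seeded white-noise carrier is band-pass filtered to the
#' channel range, multiplied sample-wise by the channel envelope, band-pass
#' filtered again with the same filter, and all channels are summed. A fixed
#' seed gives bit-identical output.
#'
#' @param env An [envelope_matrix()] with N rows.
#' @param edges A [band_edges()] with N bands.
#' @param spec A [filter_spec()].
#' @param seed Integer seed for the noise carriers.
#' @return An [audio_signal()] of the same length as the envelopes.
#' @export
synthesize <- function(env, edges, spec = filter_spec(), seed = 1L) {
  stopifnot(inherits(env, "envelope_matrix"), inherits(edges, "band_edges"))
  n <- nrow(env$values)
  if (n != n_bands(edges)) {
    stop("envelope has ", n, " channels but edges define ", n_bands(edges),
         " bands", call. = FALSE)
  }
  len <- ncol(env$values)
  out <- numeric(len)
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  for (i in seq_len(n)) {
    sos <- butter_bandpass_sos(spec$bandpass_order,
                               edges$edges[i], edges$edges[i + 1], env$fs)
    carrier <- sos_filter(sos, stats::rnorm(len))
    modulated <- carrier * env$values[i, ]
    out <- out + sos_filter(sos, modulated)
  }
  audio_signal(out, env$fs)
}

#' Run the full noise-vocoder chain
#'
#' Band-pass analysis, envelope extraction, dynamic-range limiting, dB
#' quantization, and noise-carrier synthesis, in that fixed order. With
#' `dynamic_range_db = "full"` and `quant_steps = "infinite"` the degradation
#' stages are identities and the output is the classic noise vocoder. The
#' output is rescaled to the input RMS so presentation level is comparable
#' across conditions.
#'
#' @param signal A mono [audio_signal()]; `fs >= 16000` required when the top
#'   band edge reaches 7900 Hz.
#' @param params A [vocoder_params()].
#' @return A vocoded [audio_signal()] of the same length as the input.
#' @export
vocode <- function(signal, params = vocoder_params()) {
  stopifnot(inherits(signal, "audio_signal"), inherits(params, "vocoder_params"))
  edges <- edges_for(params)
  f_top <- max(edges$edges)
  if (f_top >= 7900 && signal$fs < 16000) {
    stop("sampling rate ", signal$fs, " Hz too low for a ", f_top,
         " Hz band edge; need fs >= 16000 Hz (resample the input first)",
         call. = FALSE)
  }
  bands <- split_bands(signal, edges, params$filter_spec)
  env <- extract_envelopes(bands, params$env_cutoff, params$filter_spec)
  env <- limit_dynamic_range(env, params$dynamic_range_db)
  if (!identical(params$quant_steps, "infinite")) {
    env <- quantize_envelopes(env, params$quant_steps, params$dynamic_range_db)
  }
  out <- synthesize(env, edges, params$filter_spec, params$carrier_seed)
  in_rms <- rms(signal)
  out_rms <- rms(out)
  if (in_rms > 0 && out_rms > 0) {
    out$samples <- out$samples * (in_rms / out_rms)
  }
  out
}
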