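#' Band-edge container
#'
#' N+1 strictly increasing boundary frequencies in Hz defining N
#' non-overlapping analysis/synthesis bands (one band per vocoder channel,
#' simulating one implant electrode each).
#'
#' @param edges Numeric vector of N+1 boundary frequencies in Hz.
#' @return An object of class `band_edges`.
#' @export
band_edges <- function(edges) {
  edges <- as.numeric(edges)
  if (length(edges) < 2) {
    stop("need at least 2 edges (1 band)", call. = FALSE)
  }
  if (any(!is.finite(edges)) || any(edges <= 0)) {
    stop("all edges must be finite and > 0 Hz", call. = FALSE)
  }
  if (any(diff(edges) <= 0)) {
    stop("edges must be strictly increasing", call. = FALSE)
  }
  structure(list(edges = edges), class = "band_edges")
}

#' @export
print.band_edges <- function(x, ...) {
  cat(sprintf("<band_edges: %d bands, %g-%g Hz>\n",
              n_bands(x), x$edges[1], x$edges[length(x$edges)]))
  invisible(x)
}

#' Number of bands defined by a `band_edges` object
#' @param x A [band_edges()] object.
#' @export
n_bands <- function(x) {
  stopifnot(inherits(x, "band_edges"))
  length(x$edges) - 1L
}

#' Filter design specification
#'
#' Orders of the Butterworth filters used throughout the vocoder chain.
#' `bandpass_order` counts total poles of each band-pass filter (6 poles =
#' 3 conjugate pole pairs, the usual reading of a "sixth-order" vocoder
#' band filter); set `bandpass_order = 12` to interpret the band-pass as a
#' 6th-order low-pass prototype instead. Filtering is causal (forward only),
#' mirroring real-time implant processing; set `zero_phase = TRUE` for
#' forward-backward filtering.
#'
#' @param bandpass_order Poles per band-pass filter; even, positive. Default 6.
#' @param lowpass_order Poles of the envelope low-pass filter. Default 4.
#' @param zero_phase Apply filters forward-backward instead of causally.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(bandpass_order = 6L, lowpass_order = 4L,
                        zero_phase = FALSE) {
  if (bandpass_order < 2 || bandpass_order %% 2 != 0) {
    stop("`bandpass_order` must be a positive even pole count", call. = FALSE)
  }
  if (lowpass_order < 1) {
    stop("`lowpass_order` must be positive", call. = FALSE)
  }
  structure(
    list(bandpass_order = as.integer(bandpass_order),
         lowpass_order = as.integer(lowpass_order),
         zero_phase = isTRUE(zero_phase)),
    class = "filter_spec"
  )
}

#' Equal-octave channel boundaries
#'
#' Converts the overall frequency range to octaves, divides it by the number
#' of channels, and lays out boundaries at equal octave spacing:
#' `edges[k] = f_low * (f_high/f_low)^(k/n)`, so every channel spans the same
#' number of octaves.
#'
#' @param f_low,f_high Overall frequency range in Hz; `0 < f_low < f_high`.
#' @param n Number of channels (>= 1).
#' @return A [band_edges()] with `n + 1` boundaries.
#' @examples
#' equal_octave_edges(200, 3200, 4) # exact octaves: 200 400 800 1600 3200
#' @export
equal_octave_edges <- function(f_low, f_high, n) {
  if (!is.numeric(f_low) || !is.numeric(f_high) ||
      f_low <= 0 || f_high <= f_low) {
    stop("need 0 < f_low < f_high", call. = FALSE)
  }
  if (n < 1) stop("`n` must be >= 1", call. = FALSE)
  k <- 0:n
  band_edges(f_low * (f_high / f_low)^(k / n))
}

#' Device-standard channel boundaries
#'
#' Returns the bundled frequency-allocation table for the Cochlear Ltd.
#' standard filterbank (188-7938 Hz). The bundled table covers 22 channels;
#' other channel counts require a user-supplied table file.
#'
#' @param n Channel count with a bundled or configured table entry.
#' @param table Path to a YAML table mapping channel counts to edge lists;
#'   defaults to the bundled device table.
#' @return A [band_edges()].
#' @export
cochlear_edges <- function(n,
                           table = system.file("extdata", "cochlear_bands.yaml",
                                               package = "vocsim")) {
  tab <- yaml::read_yaml(table)
  key <- as.character(as.integer(n))
  if (is.null(tab[[key]])) {
    stop("unsupported configuration: no device band table for n = ", n,
         " channels in ", table, call. = FALSE)
  }
  edges <- band_edges(as.numeric(tab[[key]]))
  if (n_bands(edges) != as.integer(n)) {
    stop("band table for n = ", n, " has ", n_bands(edges), " bands", call. = FALSE)
  }
  edges
}

#' Band-pass analysis filtering
#'
#' Passes a signal through N non-overlapping Butterworth band-pass filters
#' (cascaded second-order sections). Each output has the same length as the
#' input.
#'
#' @param signal An [audio_signal()].
#' @param edges A [band_edges()]; highest edge must lie below Nyquist.
#' @param spec A [filter_spec()].
#' @return List of N `audio_signal` objects, one per band.
#' @export
split_bands <- function(signal, edges, spec = filter_spec()) {
  stopifnot(inherits(signal, "audio_signal"), inherits(edges, "band_edges"))
  if (length(signal$samples) == 0) {
    stop("empty signal", call. = FALSE)
  }
  nyq <- signal$fs / 2
  if (max(edges$edges) >= nyq) {
    stop("highest band edge (", max(edges$edges), " Hz) at/above Nyquist (",
         nyq, " Hz)", call. = FALSE)
  }
  lapply(seq_len(n_bands(edges)), function(i) {
    sos <- butter_bandpass_sos(spec$bandpass_order,
                               edges$edges[i], edges$edges[i + 1], signal$fs)
    y <- sos_filter(sos, signal$samples)
    if (spec$zero_phase) {
      y <- rev(sos_filter(sos, rev(y)))
    }
    audio_signal(y, signal$fs)
  })
}
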