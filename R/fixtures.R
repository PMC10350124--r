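# Synthetic test stimuli and a scriptable mock recognizer. Real clinical
# speech corpora (AzBio/CNC/IEEE) are licensed and cannot be bundled;
# harmonic complexes with known amplitude modulators make every stage of the
# pipeline testable (envelope recovery against the analytic modulator,
# scoring against scripted transcriptions) without any corpus or ASR model.

#' Synthesize a harmonic AM test stimulus
#'
#' A harmonic complex (fundamental plus harmonics, seeded random phases) with
#' sinusoidal amplitude modulation. Returns both the waveform and the analytic
#' modulator, so envelope-recovery accuracy can be measured exactly.
#'
#' @param f0 Fundamental frequency in Hz.
#' @param n_harmonics Number of harmonics (all below Nyquist, or error).
#' @param am_rate Modulation rate in Hz.
#' @param am_depth Modulation depth in `[0, 1]`; 0 gives a constant modulator.
#' @param dur Duration in seconds.
#' @param fs Sample rate in Hz.
#' @param seed Integer seed (harmonic phases).
#' @return List with `audio` (an [audio_signal()]) and `envelope` (numeric
#'   vector, the ideal modulator sampled at `fs`).
#' @examples
#' st <- synth_stimulus(f0 = 200, n_harmonics = 10, am_rate = 8)
#' length(st$audio)
#' @export
synth_stimulus <- function(f0 = 200, n_harmonics = 10, am_rate = 8,
                           am_depth = 1, dur = 1, fs = 16000, seed = 1L) {
  if (am_depth < 0 || am_depth > 1) {
    stop("`am_depth` must be in [0, 1]", call. = FALSE)
  }
  if (f0 * n_harmonics >= fs / 2) {
    stop("harmonics reach ", f0 * n_harmonics,
         " Hz, at/above Nyquist: aliasing", call. = FALSE)
  }
  n <- round(dur * fs)
  t <- (seq_len(n) - 1) / fs
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  phases <- stats::runif(n_harmonics, 0, 2 * pi)
  carrier <- numeric(n)
  for (k in seq_len(n_harmonics)) {
    carrier <- carrier + sin(2 * pi * k * f0 * t + phases[k])
  }
  modulator <- 1 + am_depth * sin(2 * pi * am_rate * t)
  list(
    audio = audio_signal(modulator * carrier / n_harmonics, fs),
    envelope = modulator
  )
}

#' Assemble a word-list audio clip
#'
#' Concatenates word clips with silent gaps and zero-pads the result to a
#' fixed total duration (default 30 s, the clip length a block recognizer
#' consumes whole). The transcript is the token order.
#'
#' @param clips List of `list(audio = <audio_signal>, token = <string>)`
#'   entries, or a tibble/data.frame with list-column `audio` and column
#'   `token`.
#' @param gap Silent gap between words, in seconds.
#' @param total Total output duration in seconds; content longer than this is
#'   an error.
#' @return List with `audio` (an [audio_signal()] of exactly `total` seconds)
#'   and `transcript` (character vector of tokens).
#' @export
build_word_list_audio <- function(clips, gap = 0.2, total = 30) {
  if (is.data.frame(clips)) {
    clips <- purrr::map2(clips$audio, clips$token,
                         function(a, tok) list(audio = a, token = tok))
  }
  if (length(clips) == 0) stop("no clips", call. = FALSE)
  fs <- clips[[1]]$audio$fs
  gap_n <- round(gap * fs)
  pieces <- list()
  tokens <- character(0)
  for (i in seq_along(clips)) {
    a <- clips[[i]]$audio
    stopifnot(inherits(a, "audio_signal"))
    if (a$fs != fs) stop("clip sample rates differ", call. = FALSE)
    pieces[[length(pieces) + 1]] <- a$samples
    if (i < length(clips)) pieces[[length(pieces) + 1]] <- numeric(gap_n)
    tokens <- c(tokens, clips[[i]]$token)
  }
  content <- unlist(pieces)
  total_n <- round(total * fs)
  if (length(content) > total_n) {
    stop("clips + gaps (", round(length(content) / fs, 2),
         " s) exceed the total duration (", total, " s)", call. = FALSE)
  }
  list(
    audio = audio_signal(c(content, numeric(total_n - length(content))), fs),
    transcript = tokens
  )
}

#' Token-level transcription error model
#'
#' Seeded substitution/deletion/insertion noise applied to scripted
#' transcriptions, emulating a recognizer that misses words or splits one
#' word into several.
#'
#' @param p_sub,p_del,p_ins Per-token probabilities in `[0, 1]`.
#' @param vocabulary Token pool drawn from for substitutions/insertions.
#' @param seed Integer seed; the model keeps its own RNG stream, so a rerun
#'   with a fresh model and the same call order reproduces the corruption.
#' @return An object of class `error_model`.
#' @export
error_model <- function(p_sub = 0, p_del = 0, p_ins = 0,
                        vocabulary = letters, seed = 1L) {
  for (p in c(p_sub, p_del, p_ins)) {
    if (p < 0 || p > 1) stop("probabilities must be in [0, 1]", call. = FALSE)
  }
  state <- new.env(parent = emptyenv())
  state$rng <- NULL
  corrupt <- function(tokens) {
    old_seed <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
    if (is.null(state$rng)) {
      set.seed(seed)
    } else {
      assign(".Random.seed", state$rng, envir = globalenv())
    }
    out <- character(0)
    for (tok in tokens) {
      u <- stats::runif(1)
      if (u < p_del) {
        # dropped
      } else if (u < p_del + p_sub) {
        out <- c(out, sample(vocabulary, 1))
      } else {
        out <- c(out, tok)
      }
      if (stats::runif(1) < p_ins) {
        out <- c(out, sample(vocabulary, 1))
      }
    }
    state$rng <- get(".Random.seed", envir = globalenv())
    out
  }
  structure(list(p_sub = p_sub, p_del = p_del, p_ins = p_ins,
                 vocabulary = vocabulary, seed = seed, corrupt = corrupt),
            class = "error_model")
}

#' Scriptable mock recognizer
#'
#' A recognizer that returns scripted text per stimulus id, optionally
#' corrupted by an [error_model()]. With no error model it is the identity
#' recognizer: the clean pipeline scores 100%. Unknown stimulus ids yield an
#' empty transcription with a message.
#'
#' @param script Named character vector mapping stimulus id to the text the
#'   recognizer should "hear".
#' @param errors Optional [error_model()].
#' @return A [recognizer()] contract object.
#' @export
mock_recognizer <- function(script, errors = NULL) {
  stopifnot(is.character(script), !is.null(names(script)))
  if (!is.null(errors)) stopifnot(inherits(errors, "error_model"))
  transcribe <- function(audio, id) {
    if (!id %in% names(script)) {
      message("mock recognizer: unknown stimulus id \"", id,
              "\"; returning empty transcription")
      return("")
    }
    text <- script[[id]]
    if (is.null(errors)) {
      return(text)
    }
    paste(errors$corrupt(clean_text(text)), collapse = " ")
  }
  recognizer(transcribe, name = "mock", stochastic = !is.null(errors))
}
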