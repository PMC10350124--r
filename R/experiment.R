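#' Recognizer contract
#'
#' Wraps any audio-to-text recognizer for use by [run_experiment()]. The only
#' requirement is a `transcribe(audio, id)` function returning a character
#' string for any clip up to 30 s. External ASR engines are plugged in by
#' wrapping their invocation here; the package itself ships only the
#' deterministic [mock_recognizer()].
#'
#' @param transcribe Function `(audio_signal, id) -> character string`.
#' @param name Recognizer name for results tables.
#' @param stochastic Whether repeated calls on the same audio may differ.
#' @return An object of class `recognizer`.
#' @export
recognizer <- function(transcribe, name = "recognizer", stochastic = FALSE) {
  stopifnot(is.function(transcribe))
  structure(list(transcribe = transcribe, name = name,
                 stochastic = isTRUE(stochastic)),
            class = "recognizer")
}

#' @export
print.recognizer <- function(x, ...) {
  cat(sprintf("<recognizer: %s%s>\n", x$name,
              if (x$stochastic) " (stochastic)" else ""))
  invisible(x)
}

# Deterministic 32-bit-safe seed derivation from a base seed and indices
derive_seed <- function(base, i = 0, j = 0, k = 0) {
  m <- 2147483647
  s <- (as.numeric(base) %% m)
  s <- (s * 48271 + i * 100003 + j * 10007 + k * 101 + 1) %% m
  as.integer(s)
}

default_condition <- function() {
  list(n_channels = 8L, edge_mode = "equal_octave", f_low = 200, f_high = 7900,
       env_cutoff = 100, dynamic_range_db = "full", quant_steps = "infinite")
}

paper_ranges <- list(
  n_channels = c(4, 6, 8, 10, 12, 16, 22),
  env_cutoff = c(5, 400),
  dynamic_range_db = c(10, 150),
  quant_steps = c(1, 100),
  f_low = c(188, 2000),
  f_high = c(2000, 7938)
)

check_condition_value <- function(param, value, strict) {
  if (identical(value, "full") || identical(value, "infinite")) {
    return(invisible())
  }
  rng <- paper_ranges[[param]]
  if (is.null(rng)) {
    return(invisible())
  }
  bad <- if (param == "n_channels") {
    !value %in% rng
  } else {
    value < rng[1] || value > rng[2]
  }
  if (bad) {
    msg <- paste0("`", param, "` value ", value,
                  " outside the study's tested range")
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  invisible()
}

#' Build a condition grid from an experiment configuration
#'
#' Expands the Cartesian product of all swept vocoder parameter values and
#' noise conditions into a tibble, one labelled row per condition. Unswept
#' parameters take their standard defaults (8 equal-octave channels over
#' 200-7900 Hz, 100 Hz envelope cutoff, full dynamic range, continuous
#' envelopes, quiet).
#'
#' @param config A list (or path to a YAML file) with elements:
#'   `sweep` (named list: parameter -> vector of values; required, non-empty),
#'   `defaults` (named list overriding unswept parameters), `snr` (vector of
#'   SNRs in dB and/or `"quiet"`; default `"quiet"`), `material`
#'   (`"sentences"` or `"word_lists"`; default `"sentences"`).
#' @param strict Error (instead of warn) on values outside the study's
#'   tested ranges.
#' @return A tibble with one row per condition: `label`, all vocoder
#'   parameters, `snr`, `material`. Deterministic row order.
#' @examples
#' grid <- build_condition_grid(list(
#'   sweep = list(n_channels = c(4, 6)),
#'   snr = list("quiet", 5)
#' ))
#' nrow(grid) # 4
#' @export
build_condition_grid <- function(config, strict = FALSE) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  sweep <- config$sweep
  if (is.null(sweep) || length(sweep) == 0) {
    stop("config must sweep at least one parameter", call. = FALSE)
  }
  known <- names(default_condition())
  unknown <- setdiff(names(sweep), known)
  if (length(unknown) > 0) {
    stop("unknown sweep parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  base <- utils::modifyList(default_condition(), config$defaults %||% list())
  snrs <- config$snr %||% list("quiet")
  if (!is.list(snrs)) snrs <- as.list(snrs)
  material <- config$material %||% "sentences"
  if (!material %in% c("sentences", "word_lists")) {
    stop("`material` must be \"sentences\" or \"word_lists\"", call. = FALSE)
  }

  sweep <- lapply(sweep, function(v) if (is.list(v)) v else as.list(v))
  for (param in names(sweep)) {
    for (v in sweep[[param]]) check_condition_value(param, v, strict)
  }

  combos <- expand.grid(c(sweep, list(snr = snrs)),
                        stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  rows <- purrr::map(seq_len(nrow(combos)), function(i) {
    cond <- base
    for (param in names(sweep)) cond[[param]] <- combos[[param]][[i]]
    snr <- combos$snr[[i]]
    swept_bits <- vapply(names(sweep), function(p) {
      paste0(p, "=", format(cond[[p]]))
    }, character(1))
    label <- paste(c(swept_bits, paste0("snr=", format(snr))), collapse = " ")
    tibble::tibble(
      label = label,
      n_channels = as.integer(cond$n_channels),
      edge_mode = cond$edge_mode,
      f_low = as.numeric(cond$f_low),
      f_high = as.numeric(cond$f_high),
      env_cutoff = as.numeric(cond$env_cutoff),
      dynamic_range_db = as.character(cond$dynamic_range_db),
      quant_steps = as.character(cond$quant_steps),
      snr = as.character(snr),
      material = material
    )
  })
  grid <- dplyr::bind_rows(rows)
  if (anyDuplicated(grid$label)) {
    stop("condition labels not unique", call. = FALSE)
  }
  grid
}

params_from_row <- function(row, carrier_seed, paper_mode = FALSE) {
  dr <- row$dynamic_range_db
  if (!identical(dr, "full")) dr <- as.numeric(dr)
  qs <- row$quant_steps
  if (!identical(qs, "infinite")) qs <- as.integer(qs)
  vocoder_params(
    n_channels = row$n_channels, edge_mode = row$edge_mode,
    f_low = row$f_low, f_high = row$f_high, env_cutoff = row$env_cutoff,
    dynamic_range_db = dr, quant_steps = qs,
    carrier_seed = carrier_seed, paper_mode = paper_mode
  )
}

#' Run a vocoder recognition experiment
#'
#' For each condition and repetition, every stimulus is (optionally) mixed
#' with speech-shaped noise at the condition's SNR, vocoded with a
#' repetition-derived carrier seed, transcribed by the recognizer, and scored
#' with the material-appropriate scorer (order-insensitive pooled sentence
#' scoring, or per-list word alignment). All randomness derives
#' deterministically from `base_seed`, so a rerun with a deterministic
#' recognizer reproduces the results exactly.
#'
#' @param stimuli A tibble/data.frame with columns `id` (character), `audio`
#'   (list of [audio_signal()]), `transcript` (character, raw text).
#' @param grid Condition tibble from [build_condition_grid()].
#' @param recog A [recognizer()].
#' @param reps Repetitions per condition (default 5).
#' @param base_seed Integer master seed.
#' @param phonetic Optional phonetic backend passed to the scorers.
#' @param fixed_stimuli Freeze carrier/noise seeds across repetitions so only
#'   recognizer stochasticity varies between repetitions.
#' @param mix_after_vocoding Add noise to the vocoded signal instead of
#'   vocoding the mixture (default: the mixture is vocoded).
#' @param verbose Log per-condition progress to stderr.
#' @return An object of class `vocoder_experiment`: per-repetition scores,
#'   the condition grid, and run metadata. See [summarize_experiment()],
#'   [generics::tidy()], [ggplot2::autoplot()].
#' @export
run_experiment <- function(stimuli, grid, recog, reps = 5, base_seed = 1L,
                           phonetic = NULL, fixed_stimuli = FALSE,
                           mix_after_vocoding = FALSE, verbose = FALSE) {
  stopifnot(inherits(recog, "recognizer"))
  if (nrow(grid) == 0) stop("empty condition grid", call. = FALSE)
  if (reps < 1) stop("`reps` must be >= 1", call. = FALSE)
  stimuli <- tibble::as_tibble(stimuli)
  if (nrow(stimuli) == 0) stop("no stimuli", call. = FALSE)
  stopifnot(all(c("id", "audio", "transcript") %in% names(stimuli)))

  score_rows <- list()
  for (ci in seq_len(nrow(grid))) {
    cond <- grid[ci, ]
    if (verbose) {
      message(sprintf("[%d/%d] %s", ci, nrow(grid), cond$label))
    }
    for (rep in seq_len(reps)) {
      seed_rep <- if (fixed_stimuli) 1L else rep
      results <- character(nrow(stimuli))
      for (si in seq_len(nrow(stimuli))) {
        audio <- stimuli$audio[[si]]
        params <- params_from_row(cond, derive_seed(base_seed, ci, seed_rep, si))
        if (cond$snr != "quiet") {
          noise <- speech_shaped_noise(
            stimuli$audio, duration(audio), audio$fs,
            seed = derive_seed(base_seed, ci, seed_rep, si + 500000)
          )
          if (mix_after_vocoding) {
            voc <- vocode(audio, params)
            voc <- mix_at_snr(voc, noise, as.numeric(cond$snr))
          } else {
            voc <- vocode(mix_at_snr(audio, noise, as.numeric(cond$snr)), params)
          }
        } else {
          voc <- vocode(audio, params)
        }
        results[si] <- tryCatch(
          as.character(recog$transcribe(voc, stimuli$id[[si]])),
          error = function(e) {
            message("recognizer failed on \"", stimuli$id[[si]], "\": ",
                    conditionMessage(e), " (recorded as empty)")
            ""
          }
        )
      }
      sc <- if (cond$material == "sentences") {
        score_sentences(results, stimuli$transcript, phonetic = phonetic)
      } else {
        per <- purrr::map2(results, stimuli$transcript, function(r, t) {
          align_and_score_words(r, t, phonetic = phonetic)
        })
        pooled <- dplyr::bind_rows(per)
        score_result(sum(pooled$n_correct), sum(pooled$n_total))
      }
      score_rows[[length(score_rows) + 1]] <-
        tibble::add_column(sc, label = cond$label, rep = rep, .before = 1)
    }
  }
  structure(
    list(
      scores = dplyr::bind_rows(score_rows),
      conditions = grid,
      reps = as.integer(reps),
      base_seed = as.integer(base_seed),
      recognizer = recog$name,
      n_stimuli = nrow(stimuli)
    ),
    class = "vocoder_experiment"
  )
}

#' @export
print.vocoder_experiment <- function(x, ...) {
  cat(sprintf(
    "<vocoder_experiment: %d conditions x %d reps x %d stimuli (%s)>\n",
    nrow(x$conditions), x$reps, x$n_stimuli, x$recognizer))
  print(summarize_experiment(x))
  invisible(x)
}

#' Summarize an experiment per condition
#'
#' One row per condition with all parameter values, mean percent correct over
#' repetitions, the sample standard deviation (0 when there is a single
#' repetition), the standard error of the mean, and the repetition count.
#'
#' @param result A `vocoder_experiment` from [run_experiment()].
#' @return A tibble, one row per condition, in grid order.
#' @export
summarize_experiment <- function(result) {
  stopifnot(inherits(result, "vocoder_experiment"))
  if (nrow(result$scores) == 0) stop("empty experiment result", call. = FALSE)
  agg <- result$scores |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(
      mean_percent = mean(.data$percent),
      sd_percent = if (dplyr::n() > 1) stats::sd(.data$percent) else 0,
      sem_percent = (if (dplyr::n() > 1) stats::sd(.data$percent) else 0) /
        sqrt(dplyr::n()),
      n_reps = dplyr::n(),
      .groups = "drop"
    )
  dplyr::left_join(result$conditions, agg, by = "label")
}

#' Total stimulus presentations implied by a design
#'
#' The scale arithmetic of a condition-grid experiment: items per set, times
#' repetitions, times conditions.
#'
#' @param n_items Stimuli per set (e.g. 60 sentences, 200 words).
#' @param reps Repetitions per condition.
#' @param n_conditions Conditions in the grid.
#' @return Total presentations as a double.
#' @export
presentation_count <- function(n_items, reps, n_conditions) {
  as.numeric(n_items) * as.numeric(reps) * as.numeric(n_conditions)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @describeIn run_experiment Per-repetition scores joined with condition
#'   parameters (broom-style).
#' @param x A `vocoder_experiment`.
#' @param ... Unused.
#' @export
tidy.vocoder_experiment <- function(x, ...) {
  dplyr::left_join(x$scores, x$conditions, by = "label") |>
    dplyr::relocate("label")
}

#' @describeIn run_experiment One-row experiment overview (broom-style).
#' @export
glance.vocoder_experiment <- function(x, ...) {
  s <- summarize_experiment(x)
  tibble::tibble(
    n_conditions = nrow(x$conditions),
    n_reps = x$reps,
    n_stimuli = x$n_stimuli,
    n_presentations = presentation_count(x$n_stimuli, x$reps, nrow(x$conditions)),
    mean_percent = mean(s$mean_percent),
    min_percent = min(s$mean_percent),
    max_percent = max(s$mean_percent),
    recognizer = x$recognizer
  )
}

#' Write experiment results to CSV and JSON
#'
#' CSV carries the per-condition summary (one row per condition); JSON the
#' full per-repetition scores.
#'
#' @param result A `vocoder_experiment`.
#' @param csv,json Output paths (either may be `NULL` to skip).
#' @return `result`, invisibly.
#' @export
write_results <- function(result, csv = NULL, json = NULL) {
  stopifnot(inherits(result, "vocoder_experiment"))
  if (!is.null(csv)) {
    utils::write.csv(summarize_experiment(result), csv, row.names = FALSE)
  }
  if (!is.null(json)) {
    jsonlite::write_json(
      list(
        meta = list(reps = result$reps, base_seed = result$base_seed,
                    recognizer = result$recognizer,
                    n_stimuli = result$n_stimuli),
        scores = result$scores
      ),
      json, auto_unbox = TRUE, digits = NA
    )
  }
  invisible(result)
}
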