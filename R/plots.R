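#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an envelope matrix
#'
#' Channel-by-time heat map of envelope amplitude in dB relative to the
#' global maximum.
#'
#' @param object An [envelope_matrix()].
#' @param floor_db Display floor in dB below the maximum.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.envelope_matrix <- function(object, floor_db = 60, ...) {
  m <- max(object$values)
  if (m == 0) m <- 1
  nch <- nrow(object$values)
  nt <- ncol(object$values)
  df <- tibble::tibble(
    channel = rep(seq_len(nch), times = nt),
    time = rep((seq_len(nt) - 1) / object$fs, each = nch),
    level_db = pmax(20 * log10(pmax(as.vector(object$values) / m, 1e-12)),
                    -floor_db)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$time, factor(.data$channel),
                                   fill = .data$level_db)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "dB re max") +
    ggplot2::labs(x = "Time (s)", y = "Channel") +
    ggplot2::theme_minimal()
}

#' Plot experiment results
#'
#' Mean percent correct (error bars: +/- 1 SD over repetitions) against a
#' chosen swept parameter, one line per noise condition.
#'
#' @param object A `vocoder_experiment` from [run_experiment()].
#' @param x Name of the condition column for the x axis (default
#'   `"n_channels"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vocoder_experiment <- function(object, x = "n_channels", ...) {
  s <- summarize_experiment(object)
  if (!x %in% names(s)) {
    stop("no condition column named \"", x, "\"", call. = FALSE)
  }
  ggplot2::ggplot(s, ggplot2::aes(.data[[x]], .data$mean_percent,
                                  colour = .data$snr, group = .data$snr)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_percent - .data$sd_percent,
                   ymax = .data$mean_percent + .data$sd_percent),
      width = 0
    ) +
    ggplot2::ylim(0, 100) +
    ggplot2::labs(x = x, y = "Percent correct", colour = "SNR (dB)") +
    ggplot2::theme_minimal()
}
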