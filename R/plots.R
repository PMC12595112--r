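#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a waveform
#'
#' @param object A [audio_signal()].
#' @param max_points Cap on plotted samples (the waveform is thinned evenly
#'   above it).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ci_audio
#' @export
autoplot.ci_audio <- function(object, max_points = 4000, ...) {
  df <- as_tibble.ci_audio(object)
  if (nrow(df) > max_points) {
    df <- df[seq(1, nrow(df), length.out = max_points), ]
  }
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$amplitude)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time [s]", y = "amplitude") +
    ggplot2::theme_minimal()
}

#' Plot an amplitude spectrum
#'
#' @param signal A [audio_signal()].
#' @param fmax Upper frequency limit of the plot in Hz.
#' @param floor_db Spectrum floor in dB re the maximum.
#' @return A ggplot object.
#' @export
plot_spectrum <- function(signal, fmax = 10000, floor_db = -90) {
  sp <- spectrum_tbl(signal)
  sp <- sp[sp$freq <= fmax, ]
  sp$db <- pmax(20 * log10(pmax(sp$amplitude, 1e-12)), floor_db)
  ggplot2::ggplot(sp, ggplot2::aes(.data$freq, .data$db)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "frequency [Hz]", y = "magnitude [dB re max]") +
    ggplot2::theme_minimal()
}

#' Plot a band-envelope matrix (electrodogram-style)
#'
#' @param object An envelope matrix from [fft_decompose()] or
#'   [select_maxima()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ci_envelope
#' @export
autoplot.ci_envelope <- function(object, ...) {
  hop <- attr(object, "hop") %||% 32L
  rate <- attr(object, "rate") %||% 16000
  df <- tidyr::expand_grid(
    frame = seq_len(nrow(object)), band = seq_len(ncol(object))
  )
  df$envelope <- as.vector(object[cbind(df$frame, df$band)])
  df$time <- (df$frame - 1) * hop / rate
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$band,
                                   fill = .data$envelope)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "time [s]", y = "band", fill = "envelope") +
    ggplot2::theme_minimal()
}

#' Plot catalog stage-usage counts
#'
#' @param object A [catalog_summary()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ci_catalog_summary
#' @export
autoplot.ci_catalog_summary <- function(object, ...) {
  df <- object$usage
  df$kind <- stats::reorder(df$kind, df$n_participants)
  ggplot2::ggplot(df, ggplot2::aes(.data$n_participants, .data$kind)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "participants using the modification", y = NULL) +
    ggplot2::theme_minimal()
}
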