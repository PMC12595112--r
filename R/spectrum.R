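#' One-sided amplitude spectrum of a signal
#'
#' Hann-windowed FFT magnitude, normalized to the maximum; resolution is
#' `rate / length(signal)` Hz per bin.
#'
#' @param signal A [audio_signal()].
#' @return A tibble with columns `freq` (Hz) and `amplitude` (linear,
#'   max = 1 unless silent).
#' @export
spectrum_tbl <- function(signal) {
  stopifnot(inherits(signal, "ci_audio"))
  x <- signal$samples
  n <- length(x)
  if (n < 2) stop("signal too short for a spectrum", call. = FALSE)
  win <- 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / n)
  mag <- Mod(stats::fft(x * win))[seq_len(n %/% 2 + 1)]
  if (max(mag) > 0) mag <- mag / max(mag)
  tibble::tibble(
    freq = (seq_len(n %/% 2 + 1) - 1) * signal$rate / n,
    amplitude = mag
  )
}

#' Dominant spectral peak of a signal
#'
#' Frequency of the largest amplitude-spectrum bin inside `[fmin, fmax]`;
#' accurate to one FFT bin (`rate / length` Hz).
#'
#' @param signal A [audio_signal()].
#' @param fmin,fmax Frequency search window in Hz.
#' @return The peak frequency in Hz.
#' @export
dominant_frequency <- function(signal, fmin = 0, fmax = Inf) {
  sp <- spectrum_tbl(signal)
  sp <- sp[sp$freq >= fmin & sp$freq <= fmax, ]
  if (!nrow(sp)) stop("no bins inside the requested window", call. = FALSE)
  sp$freq[which.max(sp$amplitude)]
}

#' Energy of a signal per vocoder analysis band
#'
#' Sums spectral energy inside each band of the 22-band table; used to
#' compare band-energy profiles before and after vocoding.
#'
#' @param signal A [audio_signal()].
#' @param table The [band_table()].
#' @return A tibble with columns `band` and `energy`.
#' @export
band_energy_profile <- function(signal, table = band_table()) {
  stopifnot(inherits(signal, "ci_audio"))
  x <- signal$samples
  n <- length(x)
  p <- Mod(stats::fft(x))^2
  freq <- (seq_len(n) - 1) * signal$rate / n
  energy <- vapply(seq_len(nrow(table)), function(k) {
    sum(p[freq >= table$lower_hz[k] & freq < table$upper_hz[k]])
  }, 0)
  tibble::tibble(band = table$band, energy = energy)
}
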