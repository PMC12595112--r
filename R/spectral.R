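#' Pitch-shift stage
#'
#' Duration-preserving pitch shift in whole semitones, -15 to +15. Every
#' spectral component at frequency f is mapped to f * 2^(semitones / 12)
#' while the signal duration is preserved (phase-vocoder time stretch
#' followed by band-limited resampling).
#'
#' @param semitones Signed integer number of semitones, |semitones| <= 15.
#' @return A stage specification (class `ci_stage_pitch_shift`).
#' @export
stage_pitch_shift <- function(semitones) {
  if (!is.numeric(semitones) || length(semitones) != 1L ||
      semitones != round(semitones)) {
    stop("`semitones` must be a whole number", call. = FALSE)
  }
  if (abs(semitones) > 15) {
    stop("`semitones` must lie between -15 and +15", call. = FALSE)
  }
  structure(list(semitones = as.integer(semitones)),
            class = c("ci_stage_pitch_shift", "ci_stage"))
}

#' Frequency-shift stage
#'
#' Shifts the whole spectrum by a fixed number of Hz via single-sideband
#' modulation: the analytic signal is multiplied by a complex exponential at
#' `delta_f` and the real part is taken. Unlike a pitch shift this moves all
#' components by a constant offset, destroying harmonic integer ratios.
#' Components shifted below 0 Hz (or above Nyquist) are discarded.
#'
#' @param delta_f Shift in Hz, between -30 and +800 in steps of 5 Hz.
#' @return A stage specification (class `ci_stage_frequency_shift`).
#' @export
stage_frequency_shift <- function(delta_f) {
  if (!is.numeric(delta_f) || length(delta_f) != 1L || !is.finite(delta_f)) {
    stop("`delta_f` must be a single number in Hz", call. = FALSE)
  }
  if (delta_f < -30 || delta_f > 800) {
    stop("`delta_f` must lie in [-30, 800] Hz", call. = FALSE)
  }
  if (abs(delta_f / 5 - round(delta_f / 5)) > 1e-9) {
    stop(sprintf("`delta_f` = %g Hz is off the 5 Hz grid", delta_f),
         call. = FALSE)
  }
  structure(list(delta_f = as.double(delta_f)),
            class = c("ci_stage_frequency_shift", "ci_stage"))
}

#' @rdname apply_stage
#' @export
apply_stage.ci_stage_pitch_shift <- function(signal, stage, ...) {
  s <- stage$semitones
  x <- signal$samples
  n <- length(x)
  if (n == 0) return(signal)
  ratio <- 2^(s / 12)
  ha <- 512L
  hs <- max(64L, as.integer(round(ha * ratio)))
  # realized ratio hs/ha is rational; exact for +/-12, < 0.1% off elsewhere
  y <- pv_time_stretch(x, ha = ha, hs = hs, nfft = 2048L)
  y <- as.numeric(signal::resample(y, ha, hs))
  if (length(y) >= n) y <- y[seq_len(n)] else y <- c(y, numeric(n - length(y)))
  audio_signal(y, signal$rate)
}

# Phase-vocoder time stretch by hs/ha: analysis hop ha, synthesis hop hs,
# Hann window of nfft samples, horizontal phase propagation. At hs == ha the
# synthesis phases equal the analysis phases and the routine is transparent
# (up to overlap-add normalization at the edges).
pv_time_stretch <- function(x, ha, hs, nfft = 2048L) {
  n <- length(x)
  win <- 0.5 - 0.5 * cos(2 * pi * (0:(nfft - 1)) / nfft)  # periodic Hann
  n_frames <- max(1L, as.integer(ceiling((n - nfft) / ha)) + 1L)
  xp <- c(x, numeric((n_frames - 1L) * ha + nfft - n))

  omega <- 2 * pi * (0:(nfft - 1)) / nfft * ha  # expected advance per hop

  out_len <- (n_frames - 1L) * hs + nfft
  out <- numeric(out_len)
  norm <- numeric(out_len)

  prev_phase <- NULL
  syn_phase <- NULL
  for (m in seq_len(n_frames)) {
    a0 <- (m - 1L) * ha
    frame <- xp[(a0 + 1):(a0 + nfft)] * win
    spec <- stats::fft(frame)
    mag <- Mod(spec)
    phase <- Arg(spec)
    if (m == 1L) {
      syn_phase <- phase
    } else {
      dphi <- phase - prev_phase - omega
      dphi <- dphi - 2 * pi * round(dphi / (2 * pi))        # wrap to (-pi, pi]
      syn_phase <- syn_phase + (omega + dphi) * (hs / ha)
    }
    prev_phase <- phase
    yframe <- Re(stats::fft(mag * exp(1i * syn_phase), inverse = TRUE)) / nfft
    s0 <- (m - 1L) * hs
    idx <- (s0 + 1):(s0 + nfft)
    out[idx] <- out[idx] + yframe * win
    norm[idx] <- norm[idx] + win^2
  }
  out <- out / pmax(norm, 1e-8)
  target <- as.integer(round(n * hs / ha))
  if (length(out) >= target) out[seq_len(target)] else c(out, numeric(target - length(out)))
}

#' @rdname apply_stage
#' @export
apply_stage.ci_stage_frequency_shift <- function(signal, stage, ...) {
  d <- stage$delta_f
  x <- signal$samples
  n <- length(x)
  if (n == 0 || d == 0) return(signal)
  rate <- signal$rate
  nyq <- rate / 2

  spec <- stats::fft(x)
  h <- numeric(n)                         # analytic-signal weights
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  f_bin <- (seq_len(n) - 1) * rate / n    # one-sided bins only carry weight
  a_spec <- spec * h
  if (d < 0) a_spec[f_bin <= -d & f_bin <= nyq] <- 0   # would land below 0 Hz
  if (d > 0) a_spec[f_bin >= nyq - d & f_bin <= nyq] <- 0  # would alias
  z <- stats::fft(a_spec, inverse = TRUE) / n
  t <- (seq_len(n) - 1) / rate
  y <- Re(z * exp(2i * pi * d * t))
  audio_signal(y, rate)
}
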