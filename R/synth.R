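# License-free synthetic test signals. The sentence generator emulates the
# gross acoustics of the study's speech material — a male-voiced three-word
# utterance, energy essentially below 8 kHz, 44.1 kHz mono — via a
# glottal-pulse-like harmonic source shaped by formant resonators,
# alternating with unvoiced noise bursts and pauses. It is a stimulus
# stand-in for licensed sentence recordings, not a speech synthesizer.

#' Specification for a synthetic sentence
#'
#' @param duration Sentence duration in seconds (> 0).
#' @param f0_start,f0_end Fundamental-frequency contour endpoints in Hz
#'   (male-typical defaults; must be positive and below 400 Hz).
#' @param seed Mandatory integer seed; the generator is a pure function of
#'   its spec.
#' @return An object of class `ci_sentence_spec`.
#' @export
sentence_spec <- function(duration = 1.8, f0_start = 130, f0_end = 100, seed) {
  if (!is.numeric(duration) || length(duration) != 1L || duration <= 0) {
    stop("`duration` must be a single positive number of seconds", call. = FALSE)
  }
  for (f in c(f0_start, f0_end)) {
    if (!is.numeric(f) || length(f) != 1L || f <= 0 || f >= 400) {
      stop("f0 contour endpoints must lie in (0, 400) Hz", call. = FALSE)
    }
  }
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L) {
    stop("`seed` is mandatory", call. = FALSE)
  }
  structure(list(duration = duration, f0_start = f0_start, f0_end = f0_end,
                 seed = as.integer(seed)),
            class = "ci_sentence_spec")
}

#' Generate a synthetic speech-like sentence
#'
#' A fixed segment plan scaled to the requested duration — four voiced
#' (formant-filtered harmonic) segments, two unvoiced noise bursts, and
#' short pauses, suggesting a three-word utterance. Formant frequencies are
#' drawn per voiced segment from male-typical ranges under the spec's seed.
#' Output is 44.1 kHz mono with at least 99 % of its spectral energy below
#' 8 kHz and peak amplitude 0.5.
#'
#' @param spec A [sentence_spec()].
#' @return A [audio_signal()] at 44 100 Hz.
#' @examples
#' s <- generate_sentence(sentence_spec(duration = 1.0, seed = 1))
#' @export
generate_sentence <- function(spec) {
  stopifnot(inherits(spec, "ci_sentence_spec"))
  rate <- 44100
  n <- round(spec$duration * rate)

  # segment plan as fractions of the duration: v voiced, u unvoiced, p pause
  plan <- list(
    c(v = 0.22), c(p = 0.05), c(u = 0.08), c(v = 0.20), c(p = 0.05),
    c(v = 0.22), c(u = 0.06), c(v = 0.12)
  )
  with_preserved_rng(spec$seed, {
    f0 <- seq(spec$f0_start, spec$f0_end, length.out = n)
    phase <- cumsum(f0) / rate
    source_wave <- 2 * (phase %% 1) - 1        # sawtooth glottal-like source

    x <- numeric(n)
    pos <- 0L
    for (seg in plan) {
      len <- round(unname(seg) * spec$duration * rate)
      len <- min(len, n - pos)
      if (len <= 0) break
      idx <- pos + seq_len(len)
      type <- names(seg)
      if (type == "v") {
        f1 <- stats::runif(1, 300, 800)
        f2 <- stats::runif(1, max(f1 + 300, 1000), 2000)
        f3 <- stats::runif(1, 2300, 3000)
        seg_x <- source_wave[idx]
        for (fc in c(f1, f2, f3)) {
          seg_x <- resonator_filter(seg_x, fc, bw = 120, rate = rate)
        }
        x[idx] <- seg_x / max(abs(seg_x)) * ramp(len, rate)
      } else if (type == "u") {
        seg_x <- stats::rnorm(len)
        seg_x <- sos_filter(seg_x, butter_sos(2, 2500, rate, "high"))
        x[idx] <- seg_x / max(abs(seg_x)) * 0.35 * ramp(len, rate)
      }
      pos <- pos + len
    }
    # keep >= 99% of energy below 8 kHz
    x <- sos_filter(x, butter_sos(6, 7000, rate, "low"))
    audio_signal(x / max(abs(x)) * 0.5, rate)
  })
}

# two-pole resonance at fc with -3 dB bandwidth bw, unity gain at fc
resonator_filter <- function(x, fc, bw, rate) {
  r <- exp(-pi * bw / rate)
  w0 <- 2 * pi * fc / rate
  a <- c(1, -2 * r * cos(w0), r^2)
  z <- exp(-1i * w0)
  g <- abs(1 / (1 + a[2] * z + a[3] * z^2))
  as.numeric(signal::filter(1 / g, a, x))
}

# raised-cosine on/off ramps (10 ms) to avoid clicks
ramp <- function(len, rate, ms = 10) {
  k <- min(round(ms / 1000 * rate), len %/% 2)
  env <- rep(1, len)
  if (k > 0) {
    up <- 0.5 - 0.5 * cos(pi * seq_len(k) / k)
    env[seq_len(k)] <- up
    env[len - k + seq_len(k)] <- rev(up)
  }
  env
}

#' Generate an equal-amplitude harmonic complex
#'
#' Partials at `k * f0`, `k = 1 ... partials`, all with the same amplitude;
#' the standard fixture for pitch-shift, frequency-shift and vocoder tests.
#'
#' @param f0 Fundamental frequency in Hz.
#' @param partials Number of partials; `f0 * partials` must stay below the
#'   Nyquist limit.
#' @param duration Duration in seconds.
#' @param rate Sampling rate in Hz.
#' @return A [audio_signal()].
#' @export
generate_harmonic_tone <- function(f0, partials, duration = 1, rate = 44100) {
  stopifnot(f0 > 0, partials >= 1, partials == round(partials), duration > 0)
  if (f0 * partials >= rate / 2) {
    stop(sprintf("%d partials of %g Hz exceed the Nyquist limit %g Hz",
                 partials, f0, rate / 2), call. = FALSE)
  }
  t <- (seq_len(round(duration * rate)) - 1) / rate
  x <- numeric(length(t))
  for (k in seq_len(partials)) x <- x + sin(2 * pi * k * f0 * t)
  audio_signal(x * (0.9 / partials), rate)
}

#' Generate a full-scale sine
#'
#' A sine normalized so its peak sample is exactly 1.0 — the fixture for
#' the clipping stage, whose bound is the input peak.
#'
#' @param freq Frequency in Hz, below Nyquist.
#' @param duration Duration in seconds.
#' @param rate Sampling rate in Hz.
#' @return A [audio_signal()] with `max(abs(samples)) == 1`.
#' @export
generate_full_scale_sine <- function(freq, duration = 1, rate = 44100) {
  stopifnot(duration > 0)
  if (freq <= 0 || freq >= rate / 2) {
    stop(sprintf("`freq` must lie in (0, %g) Hz", rate / 2), call. = FALSE)
  }
  t <- (seq_len(round(duration * rate)) - 1) / rate
  x <- sin(2 * pi * freq * t)
  audio_signal(x / max(abs(x)), rate)
}
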