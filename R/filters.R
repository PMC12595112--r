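#' Pass-filter stage (low-, high-, or band-pass)
#'
#' Causal Butterworth filtering on the clinical parameter grid: order 1-10,
#' cutoffs between 0 and 8 kHz in steps of 0.1 kHz. A low-pass takes
#' `cutoff_high`, a high-pass takes `cutoff_low`, a band-pass takes both
#' (with `cutoff_low < cutoff_high`). A `cutoff_low` of 0 kHz means "no lower
#' constraint": a band-pass degenerates to a low-pass and a high-pass to a
#' passthrough, since a true 0 Hz cutoff is undefined.
#'
#' @param kind `"low"`, `"high"` or `"band"`.
#' @param order Filter order, integer 1-10 (the slope order per edge for a
#'   band-pass).
#' @param cutoff_low,cutoff_high Cutoff frequencies in kHz on the 0.1 kHz
#'   grid, at most 8 kHz.
#' @return A stage specification (class `ci_stage_pass_filter`), usable with
#'   [apply_stage()] and inside a [parameter_set()].
#' @examples
#' lp <- stage_pass_filter("low", order = 4, cutoff_high = 2.0)
#' @export
stage_pass_filter <- function(kind = c("low", "high", "band"), order,
                              cutoff_low = NULL, cutoff_high = NULL) {
  kind <- match.arg(kind)
  if (!is.numeric(order) || length(order) != 1L || order != round(order) ||
      order < 1 || order > 10) {
    stop("`order` must be an integer between 1 and 10", call. = FALSE)
  }
  check_cutoff <- function(x, name) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
      stop(sprintf("`%s` must be a single number in kHz", name), call. = FALSE)
    }
    if (x < 0 || x > 8) {
      stop(sprintf("`%s` must lie in [0, 8] kHz", name), call. = FALSE)
    }
    if (abs(x * 10 - round(x * 10)) > 1e-9) {
      stop(sprintf("`%s` = %g kHz is off the 0.1 kHz grid", name, x),
           call. = FALSE)
    }
    round(x * 10) / 10
  }
  if (kind == "low") {
    if (is.null(cutoff_high)) stop("a low-pass needs `cutoff_high`", call. = FALSE)
    cutoff_high <- check_cutoff(cutoff_high, "cutoff_high")
    if (cutoff_high == 0) stop("a low-pass cutoff of 0 kHz is undefined", call. = FALSE)
    cutoff_low <- NULL
  } else if (kind == "high") {
    if (is.null(cutoff_low)) stop("a high-pass needs `cutoff_low`", call. = FALSE)
    cutoff_low <- check_cutoff(cutoff_low, "cutoff_low")
    cutoff_high <- NULL
  } else {
    if (is.null(cutoff_low) || is.null(cutoff_high)) {
      stop("a band-pass needs `cutoff_low` and `cutoff_high`", call. = FALSE)
    }
    cutoff_low <- check_cutoff(cutoff_low, "cutoff_low")
    cutoff_high <- check_cutoff(cutoff_high, "cutoff_high")
    if (cutoff_low >= cutoff_high) {
      stop("`cutoff_low` must be below `cutoff_high`", call. = FALSE)
    }
  }
  structure(
    list(kind = kind, order = as.integer(order),
         cutoff_low = cutoff_low, cutoff_high = cutoff_high),
    class = c("ci_stage_pass_filter", "ci_stage")
  )
}

#' Comb-filter stage
#'
#' Feedback comb whose magnitude response has unity-gain peaks spaced `f0`
#' apart (including DC) and -3 dB peak bandwidth `f0 / q`. The 44.1 kHz
#' sampling rate must be an integer multiple of `f0` (the delay-line length
#' is `44100 / f0` samples), which restricts `f0` to the divisors of 44 100
#' between 1 and 14.7 kHz; see [admissible_comb_spacings()].
#'
#' @param f0 Peak spacing in Hz, a divisor of 44 100 in \[1000, 14700\].
#' @param q Quality factor `f0 / bandwidth(-3 dB)`, between 5 and 300.
#' @return A stage specification (class `ci_stage_comb_filter`).
#' @export
stage_comb_filter <- function(f0, q) {
  if (!is.numeric(f0) || length(f0) != 1L || !is.finite(f0)) {
    stop("`f0` must be a single number in Hz", call. = FALSE)
  }
  if (f0 < 1000 || f0 > 14700) {
    stop("`f0` must lie in [1000, 14700] Hz", call. = FALSE)
  }
  if (abs(44100 / f0 - round(44100 / f0)) > 1e-9) {
    stop(sprintf("44100 Hz is not an integer multiple of f0 = %g Hz", f0),
         call. = FALSE)
  }
  if (!is.numeric(q) || length(q) != 1L || !is.finite(q) || q < 5 || q > 300) {
    stop("`q` must lie in [5, 300]", call. = FALSE)
  }
  structure(list(f0 = as.double(f0), q = as.double(q)),
            class = c("ci_stage_comb_filter", "ci_stage"))
}

#' Admissible comb-filter peak spacings
#'
#' All spacings `f0` between 1 and 14.7 kHz such that 44 100 Hz is an integer
#' multiple of `f0`. The upper end, 14.7 kHz, is the largest divisor of
#' 44 100 strictly below the 22.05 kHz Nyquist limit.
#'
#' @return Ascending numeric vector of spacings in Hz.
#' @examples
#' max(admissible_comb_spacings())  # 14700
#' @export
admissible_comb_spacings <- function() {
  d <- seq_len(44100)
  d <- d[44100 %% d == 0]
  d[d >= 1000 & d <= 14700]
}

# ---- application ----------------------------------------------------------

#' Apply a processing stage to an audio signal
#'
#' Dispatches on the stage specification class. Every stage preserves the
#' sample count and sampling rate of its input.
#'
#' @param signal A [audio_signal()].
#' @param stage A stage specification (`stage_*()` constructors).
#' @param ... Passed on to methods.
#' @return The processed [audio_signal()].
#' @export
apply_stage <- function(signal, stage, ...) {
  stopifnot(inherits(signal, "ci_audio"))
  UseMethod("apply_stage", stage)
}

#' @export
apply_stage.default <- function(signal, stage, ...) {
  stop("not a recognised processing stage", call. = FALSE)
}

#' @rdname apply_stage
#' @export
apply_stage.ci_stage_pass_filter <- function(signal, stage, ...) {
  rate <- signal$rate
  hi <- stage$cutoff_high
  if (!is.null(hi) && rate < 2 * hi * 1000) {
    stop(sprintf("sampling rate %g Hz cannot carry a %g kHz cutoff", rate, hi),
         call. = FALSE)
  }
  sos <- pass_filter_sos(stage, rate)
  if (is.null(sos)) return(signal)  # degenerate passthrough (high-pass at 0)
  audio_signal(sos_filter(signal$samples, sos), rate)
}

# stage -> SOS design at a given rate; NULL means passthrough
pass_filter_sos <- function(stage, rate) {
  lo_hz <- if (!is.null(stage$cutoff_low)) stage$cutoff_low * 1000
  hi_hz <- if (!is.null(stage$cutoff_high)) stage$cutoff_high * 1000
  switch(stage$kind,
    low  = butter_sos(stage$order, hi_hz, rate, "low"),
    high = if (lo_hz == 0) NULL else butter_sos(stage$order, lo_hz, rate, "high"),
    band = if (lo_hz == 0) {
      butter_sos(stage$order, hi_hz, rate, "low")
    } else {
      butter_sos(stage$order, c(lo_hz, hi_hz), rate, "pass")
    }
  )
}

#' @rdname apply_stage
#' @export
apply_stage.ci_stage_comb_filter <- function(signal, stage, ...) {
  if (!isTRUE(all.equal(signal$rate, 44100))) {
    stop("the comb filter is defined at a 44100 Hz sampling rate", call. = FALSE)
  }
  co <- comb_coefficients(stage$f0, stage$q, signal$rate)
  y <- as.numeric(signal::filter(co$b, co$a, signal$samples))
  audio_signal(y, signal$rate)
}

# Feedback comb H(z) = b0 (1 + z^-N) / (1 - c z^-N), N = fs / f0.
# Peaks (gain 1) at k * f0; solving |H|^2 = 1/2 gives the exact -3 dB
# bandwidth f0/q when c = (1 - tan(pi / (2 q))) / (1 + tan(pi / (2 q))).
comb_coefficients <- function(f0, q, rate) {
  n_delay <- as.integer(round(rate / f0))
  beta <- tan(pi / (2 * q))
  c_fb <- (1 - beta) / (1 + beta)
  b0 <- (1 - c_fb) / 2
  b <- numeric(n_delay + 1); b[1] <- b0; b[n_delay + 1] <- b0
  a <- numeric(n_delay + 1); a[1] <- 1;  a[n_delay + 1] <- -c_fb
  list(b = b, a = a, n_delay = n_delay)
}

# ---- frequency response (for tests, plots, documentation) -----------------

#' Magnitude response of a filter stage
#'
#' Evaluates the realized transfer function of a pass- or comb-filter stage
#' at the requested frequencies.
#'
#' @param stage A pass- or comb-filter stage specification.
#' @param freq Frequencies in Hz.
#' @param rate Sampling rate in Hz the stage would run at (default 44 100).
#' @return A tibble with columns `freq` and `magnitude` (linear gain).
#' @export
stage_response <- function(stage, freq, rate = 44100) {
  stopifnot(inherits(stage, "ci_stage"))
  if (inherits(stage, "ci_stage_pass_filter")) {
    sos <- pass_filter_sos(stage, rate)
    mag <- if (is.null(sos)) rep(1, length(freq)) else
      abs(sos_response(sos, freq, rate))
  } else if (inherits(stage, "ci_stage_comb_filter")) {
    co <- comb_coefficients(stage$f0, stage$q, rate)
    z <- exp(-2i * pi * freq / rate)
    mag <- abs((co$b[1] * (1 + z^co$n_delay)) / (1 + co$a[co$n_delay + 1] * z^co$n_delay))
  } else {
    stop("`stage_response()` is defined for pass- and comb-filter stages",
         call. = FALSE)
  }
  tibble::tibble(freq = freq, magnitude = mag)
}
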