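# 22-channel vocoders. Both run at the implant processor's 16 kHz analysis
# rate; the FFT vocoder mirrors the ACE strategy (128-point FFT with 125 Hz
# bins, channel = group of adjacent bins, n-of-m maxima selection), the BP
# vocoder replaces the FFT analysis with a Butterworth band-pass bank.

the_band_table <- new.env(parent = emptyenv())

#' The 22-band ACE analysis table
#'
#' Fixed allocation of the 125 Hz FFT bins (128-point FFT at 16 kHz) to the
#' 22 analysis channels, spanning 187.5 to 7937.5 Hz. Shipped as a tabular
#' config file (`inst/extdata/ace-band-table.csv`) so it can be audited or
#' swapped without a code change.
#'
#' @return A tibble of class `ci_band_table` with columns `band`, `bin_lo`,
#'   `bin_hi` (0-based FFT bins), `lower_hz`, `upper_hz`, `center_hz`, and
#'   attributes `processing_rate` (16000), `frame_length` (128).
#' @examples
#' nrow(band_table())  # 22
#' @export
band_table <- function() {
  if (!is.null(the_band_table$tbl)) return(the_band_table$tbl)
  path <- system.file("extdata", "ace-band-table.csv", package = "cisim")
  raw <- utils::read.csv(path, comment.char = "#")
  tbl <- tibble::as_tibble(raw)
  stopifnot(
    nrow(tbl) == 22,
    all(diff(tbl$lower_hz) > 0),
    all(tbl$upper_hz > tbl$lower_hz),
    all(tbl$upper_hz <= 8000),
    # contiguous, non-overlapping bands
    all(abs(tbl$upper_hz[-22] - tbl$lower_hz[-1]) < 1e-9)
  )
  attr(tbl, "processing_rate") <- 16000
  attr(tbl, "frame_length") <- 128L
  class(tbl) <- c("ci_band_table", class(tbl))
  the_band_table$tbl <- tbl
  tbl
}

soe_order <- function(soe = c("narrow", "moderate", "flat")) {
  soe <- match.arg(soe)
  c(narrow = 4L, moderate = 2L, flat = 1L)[[soe]]
}

#' FFT-vocoder stage
#'
#' ACE-like vocoder: 22-band FFT analysis at 16 kHz, per-frame selection of
#' the `n_selected` largest band envelopes (n-of-m), carrier resynthesis.
#' The spread of excitation (SOE) sets the slope of the noise-carrier band
#' filters: narrow, moderate, flat map to Butterworth orders 4, 2, 1.
#'
#' @param n_selected Number of maxima kept per frame, 1-22.
#' @param carrier `"sine"` or `"noise"`.
#' @param soe `"narrow"`, `"moderate"` or `"flat"`.
#' @param noise_seed Integer seed; mandatory for the noise carrier so
#'   stimuli are reproducible.
#' @return A stage specification (class `ci_stage_fft_vocoder`).
#' @export
stage_fft_vocoder <- function(n_selected, carrier = c("sine", "noise"),
                              soe = c("narrow", "moderate", "flat"),
                              noise_seed = NULL) {
  carrier <- match.arg(carrier)
  soe <- match.arg(soe)
  if (!is.numeric(n_selected) || length(n_selected) != 1L ||
      n_selected != round(n_selected) || n_selected < 1 || n_selected > 22) {
    stop("`n_selected` must be an integer between 1 and 22", call. = FALSE)
  }
  if (carrier == "noise" && is.null(noise_seed)) {
    stop("the noise carrier requires `noise_seed`", call. = FALSE)
  }
  structure(
    list(n_selected = as.integer(n_selected), carrier = carrier, soe = soe,
         noise_seed = if (!is.null(noise_seed)) as.integer(noise_seed)),
    class = c("ci_stage_fft_vocoder", "ci_stage")
  )
}

#' Band-pass-vocoder stage
#'
#' Vocoder whose analysis bank is `n_bands` contiguous Butterworth band-pass
#' filters spanning the 22-band table's range (187.5-7937.5 Hz); at
#' `n_bands = 22` the bands coincide with the FFT vocoder's. Envelopes are
#' extracted by full-wave rectification and a 4th-order 400 Hz low-pass;
#' carrier synthesis is shared with the FFT vocoder.
#'
#' @param n_bands Number of analysis bands, 1-22.
#' @inheritParams stage_fft_vocoder
#' @return A stage specification (class `ci_stage_bp_vocoder`).
#' @export
stage_bp_vocoder <- function(n_bands, carrier = c("sine", "noise"),
                             soe = c("narrow", "moderate", "flat"),
                             noise_seed = NULL) {
  carrier <- match.arg(carrier)
  soe <- match.arg(soe)
  if (!is.numeric(n_bands) || length(n_bands) != 1L ||
      n_bands != round(n_bands) || n_bands < 1 || n_bands > 22) {
    stop("`n_bands` must be an integer between 1 and 22", call. = FALSE)
  }
  if (carrier == "noise" && is.null(noise_seed)) {
    stop("the noise carrier requires `noise_seed`", call. = FALSE)
  }
  structure(
    list(n_bands = as.integer(n_bands), carrier = carrier, soe = soe,
         noise_seed = if (!is.null(noise_seed)) as.integer(noise_seed)),
    class = c("ci_stage_bp_vocoder", "ci_stage")
  )
}

# ---- analysis --------------------------------------------------------------

#' FFT filter-bank decomposition into band envelopes
#'
#' Short-time FFT analysis (Hann window) of a 16 kHz signal; the envelope of
#' each of the 22 bands is the sum of its FFT-bin magnitudes, one value per
#' frame.
#'
#' @param signal A [audio_signal()] at 16 000 Hz.
#' @param table The analysis [band_table()].
#' @param frame_length FFT length in samples (default 128, i.e. 8 ms).
#' @param hop Hop size in samples (default 32, i.e. 2 ms).
#' @return A frames x 22 matrix of nonnegative envelopes (class
#'   `ci_envelope`), with the framing stored in attributes.
#' @export
fft_decompose <- function(signal, table = band_table(),
                          frame_length = 128L, hop = 32L) {
  stopifnot(inherits(signal, "ci_audio"))
  if (!isTRUE(all.equal(signal$rate, attr(table, "processing_rate")))) {
    stop(sprintf("FFT analysis runs at %g Hz; resample first",
                 attr(table, "processing_rate")), call. = FALSE)
  }
  x <- signal$samples
  n <- length(x)
  if (n < frame_length) {
    stop("signal is shorter than one analysis frame", call. = FALSE)
  }
  win <- 0.5 - 0.5 * cos(2 * pi * (0:(frame_length - 1)) / frame_length)
  n_frames <- (n - frame_length) %/% hop + 1L

  starts <- (seq_len(n_frames) - 1L) * hop
  frames <- matrix(x[outer(seq_len(frame_length), starts, `+`)],
                   nrow = frame_length)
  spec <- Mod(stats::mvfft(frames * win))  # frame_length x n_frames

  env <- matrix(0, nrow = n_frames, ncol = nrow(table))
  for (k in seq_len(nrow(table))) {
    bins <- (table$bin_lo[k]:table$bin_hi[k]) + 1L  # 0-based -> R index
    env[, k] <- if (length(bins) == 1L) spec[bins, ] else colSums(spec[bins, , drop = FALSE])
  }
  structure(env, class = "ci_envelope",
            hop = as.integer(hop), frame_length = as.integer(frame_length),
            rate = signal$rate)
}

#' n-of-m maxima selection
#'
#' Per analysis frame, keeps the `n_selected` largest band envelopes and
#' zeroes the rest (ties broken toward the lower band index). Bands that are
#' already zero are never counted as selected, so a frame retains
#' `min(n_selected, number of nonzero bands)` entries.
#'
#' @param envelopes A frames x bands envelope matrix ([fft_decompose()]).
#' @param n_selected Number of maxima to keep, 1 to `ncol(envelopes)`.
#' @return The sparsified matrix, attributes preserved.
#' @export
select_maxima <- function(envelopes, n_selected) {
  stopifnot(is.matrix(envelopes))
  m <- ncol(envelopes)
  if (!is.numeric(n_selected) || length(n_selected) != 1L ||
      n_selected != round(n_selected) || n_selected < 1 || n_selected > m) {
    stop(sprintf("`n_selected` must be an integer between 1 and %d", m),
         call. = FALSE)
  }
  if (n_selected == m) return(envelopes)
  out <- envelopes
  for (i in seq_len(nrow(out))) {
    row <- out[i, ]
    keep <- order(row, decreasing = TRUE)[seq_len(n_selected)]
    drop <- setdiff(seq_len(m), keep)
    out[i, drop] <- 0
  }
  out
}

# ---- synthesis -------------------------------------------------------------

# carrier matrix (n_samples x n_bands): zero-phase sines at band centers, or
# seeded Gaussian noise band-passed at the SOE-mapped Butterworth order and
# normalized to the RMS of a unit sine so both carriers scale alike.
make_carriers <- function(bands, carrier, soe, noise_seed, n_samples, rate) {
  nb <- nrow(bands)
  out <- matrix(0, n_samples, nb)
  if (carrier == "sine") {
    t <- (seq_len(n_samples) - 1) / rate
    for (k in seq_len(nb)) out[, k] <- sin(2 * pi * bands$center_hz[k] * t)
    return(out)
  }
  if (is.null(noise_seed)) stop("the noise carrier requires `noise_seed`", call. = FALSE)
  ord <- soe_order(soe)
  noise <- with_preserved_rng(noise_seed, stats::rnorm(n_samples))
  for (k in seq_len(nb)) {
    sos <- butter_sos(ord, c(bands$lower_hz[k], min(bands$upper_hz[k], rate / 2 - 1)),
                      rate, "pass")
    nb_k <- sos_filter(noise, sos)
    r <- sqrt(mean(nb_k^2))
    out[, k] <- if (r > 0) nb_k * (1 / sqrt(2) / r) else nb_k
  }
  out
}

# run code under a fixed seed without disturbing the caller's RNG stream
with_preserved_rng <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (had) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Resynthesize audio from band envelopes
#'
#' Each band's envelope is linearly interpolated from the frame grid to the
#' sample grid and multiplied onto its carrier; the modulated carriers are
#' summed into a 16 kHz signal.
#'
#' @param envelopes Frames x bands matrix (typically from [select_maxima()]).
#' @param table The [band_table()] the matrix was analysed with.
#' @param carrier `"sine"` or `"noise"`.
#' @param soe Spread-of-excitation setting for the noise carrier.
#' @param noise_seed Seed for the noise carrier (mandatory with it).
#' @param n_samples Output length in samples; defaults to the span of the
#'   analysis frames.
#' @return A [audio_signal()] at the table's processing rate.
#' @export
synthesize <- function(envelopes, table = band_table(),
                       carrier = c("sine", "noise"),
                       soe = c("narrow", "moderate", "flat"),
                       noise_seed = NULL, n_samples = NULL) {
  carrier <- match.arg(carrier)
  soe <- match.arg(soe)
  stopifnot(is.matrix(envelopes))
  if (ncol(envelopes) != nrow(table)) {
    stop(sprintf("envelope matrix has %d columns but the table %d bands",
                 ncol(envelopes), nrow(table)), call. = FALSE)
  }
  hop <- attr(envelopes, "hop") %||% 32L
  frame_length <- attr(envelopes, "frame_length") %||% 128L
  rate <- attr(table, "processing_rate")
  n_frames <- nrow(envelopes)
  if (is.null(n_samples)) n_samples <- (n_frames - 1L) * hop + frame_length

  carriers <- make_carriers(table, carrier, soe, noise_seed, n_samples, rate)

  # frame anchor = frame center on the sample grid
  anchors <- (seq_len(n_frames) - 1L) * hop + frame_length / 2
  pos <- seq_len(n_samples)
  y <- numeric(n_samples)
  for (k in seq_len(ncol(envelopes))) {
    if (all(envelopes[, k] == 0)) next
    env_k <- stats::approx(anchors, envelopes[, k], xout = pos, rule = 2)$y
    y <- y + env_k * carriers[, k]
  }
  audio_signal(y, rate)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- full pipelines --------------------------------------------------------

#' @rdname apply_stage
#' @export
apply_stage.ci_stage_fft_vocoder <- function(signal, stage, ...) {
  fft_vocode(signal, stage)
}

#' @rdname apply_stage
#' @export
apply_stage.ci_stage_bp_vocoder <- function(signal, stage, ...) {
  bp_vocode(signal, stage)
}

#' Run the full FFT vocoder
#'
#' Pipeline: resample to 16 kHz, FFT band decomposition, n-of-m maxima
#' selection, carrier resynthesis, resample back to the input rate, match
#' the input RMS.
#'
#' @param signal A [audio_signal()].
#' @param spec A [stage_fft_vocoder()] specification.
#' @return The vocoded [audio_signal()] at the input's rate and RMS.
#' @export
fft_vocode <- function(signal, spec) {
  stopifnot(inherits(spec, "ci_stage_fft_vocoder"))
  tbl <- band_table()
  proc <- resample_audio(signal, attr(tbl, "processing_rate"))
  env <- fft_decompose(proc, tbl)
  env <- select_maxima(env, spec$n_selected)
  voc <- synthesize(env, tbl, carrier = spec$carrier, soe = spec$soe,
                    noise_seed = spec$noise_seed,
                    n_samples = length(proc$samples))
  out <- resample_audio(voc, signal$rate)
  out <- fit_length(out, length(signal$samples))
  match_rms(out, signal)
}

#' Run the full band-pass vocoder
#'
#' As [fft_vocode()], but the analysis is `n_bands` contiguous Butterworth
#' band-pass filters (the 22 table bands merged into `n_bands` groups) with
#' envelopes from full-wave rectification + 400 Hz low-pass; there is no
#' maxima selection.
#'
#' @param signal A [audio_signal()].
#' @param spec A [stage_bp_vocoder()] specification.
#' @return The vocoded [audio_signal()] at the input's rate and RMS.
#' @export
bp_vocode <- function(signal, spec) {
  stopifnot(inherits(spec, "ci_stage_bp_vocoder"))
  tbl <- band_table()
  rate16 <- attr(tbl, "processing_rate")
  proc <- resample_audio(signal, rate16)
  x <- proc$samples
  n <- length(x)

  groups <- bp_band_groups(tbl, spec$n_bands)
  env_lp <- butter_sos(4, 400, rate16, "low")
  y <- numeric(n)
  carriers <- make_carriers(groups, spec$carrier, spec$soe, spec$noise_seed,
                            n, rate16)
  for (k in seq_len(nrow(groups))) {
    sos <- butter_sos(4, c(groups$lower_hz[k], groups$upper_hz[k]), rate16, "pass")
    band <- sos_filter(x, sos)
    env <- sos_filter(abs(band), env_lp)
    env[env < 0] <- 0
    y <- y + env * carriers[, k]
  }
  out <- resample_audio(audio_signal(y, rate16), signal$rate)
  out <- fit_length(out, length(signal$samples))
  match_rms(out, signal)
}

# merge the 22 table bands into n contiguous groups of near-equal size
bp_band_groups <- function(tbl, n_bands) {
  edges <- round(seq(0, nrow(tbl), length.out = n_bands + 1))
  tibble::tibble(
    band = seq_len(n_bands),
    lower_hz = tbl$lower_hz[edges[-length(edges)] + 1],
    upper_hz = tbl$upper_hz[edges[-1]]
  ) |>
    dplyr::mutate(center_hz = (.data$lower_hz + .data$upper_hz) / 2)
}

fit_length <- function(signal, n) {
  x <- signal$samples
  if (length(x) >= n) x <- x[seq_len(n)] else x <- c(x, numeric(n - length(x)))
  audio_signal(x, signal$rate)
}
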