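#' Mono audio signal
#'
#' The unit every processing stage consumes and returns: a finite real
#' sample vector (nominally in \[-1, 1\]) plus a sampling rate in Hz. The
#' study material is mono speech at 44 100 Hz; stages that require a fixed
#' rate check it themselves.
#'
#' @param samples Numeric vector of finite sample amplitudes.
#' @param rate Sampling rate in Hz (single positive number).
#'
#' @return An object of class `ci_audio`.
#' @examples
#' s <- audio_signal(sin(2 * pi * 440 * seq(0, 1, by = 1 / 44100)), 44100)
#' duration(s)
#' @export
audio_signal <- function(samples, rate) {
  if (!is.numeric(samples)) {
    stop("`samples` must be a numeric vector", call. = FALSE)
  }
  samples <- as.double(samples)
  if (length(samples) && !all(is.finite(samples))) {
    stop("`samples` must be finite (no NA/NaN/Inf)", call. = FALSE)
  }
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0) {
    stop("`rate` must be a single positive number (Hz)", call. = FALSE)
  }
  structure(list(samples = samples, rate = as.double(rate)), class = "ci_audio")
}

#' @export
print.ci_audio <- function(x, ...) {
  cat(sprintf(
    "<ci_audio> %d samples @ %g Hz (%.3f s), peak %.4g, rms %.4g\n",
    length(x$samples), x$rate, duration(x),
    if (length(x$samples)) max(abs(x$samples)) else 0,
    audio_rms(x)
  ))
  invisible(x)
}

#' @export
length.ci_audio <- function(x) length(x$samples)

#' Duration of an audio signal in seconds
#' @param signal A [audio_signal()].
#' @return Duration in seconds.
#' @export
duration <- function(signal) {
  stopifnot(inherits(signal, "ci_audio"))
  length(signal$samples) / signal$rate
}

#' Root-mean-square level of an audio signal
#' @param signal A [audio_signal()].
#' @return RMS amplitude (0 for an empty signal).
#' @export
audio_rms <- function(signal) {
  stopifnot(inherits(signal, "ci_audio"))
  if (!length(signal$samples)) return(0)
  sqrt(mean(signal$samples^2))
}

#' Convert an audio signal to a tibble
#'
#' One row per sample, with time in seconds; convenient for ggplot2.
#'
#' @param x A [audio_signal()].
#' @param ... Unused.
#' @return A tibble with columns `time` and `amplitude`.
#' @importFrom tibble as_tibble
#' @method as_tibble ci_audio
#' @export
as_tibble.ci_audio <- function(x, ...) {
  tibble::tibble(
    time = (seq_along(x$samples) - 1) / x$rate,
    amplitude = x$samples
  )
}

# ---- WAV I/O ---------------------------------------------------------------
# Minimal RIFF/WAVE reader/writer: PCM 16-bit and IEEE float 32-bit, any
# channel count on read (averaged to mono), mono on write. Unknown chunks
# are skipped; that is all real-world WAV needs here.

#' Read a WAV file as a mono audio signal
#'
#' Supports 16-bit PCM and 32-bit IEEE float encodings. Multichannel files
#' are reduced to mono by averaging the channels (the simulations are
#' strictly monaural per ear). Integer PCM is rescaled to \[-1, 1\] by
#' dividing by 32768.
#'
#' @param path Path to a RIFF/WAVE file.
#' @return A [audio_signal()].
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: '%s'", path), call. = FALSE)
  }
  con <- file(path, "rb")
  on.exit(close(con))

  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) {
    stop(sprintf("unsupported encoding: '%s' is not a RIFF/WAVE file", path),
         call. = FALSE)
  }
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) {
    stop(sprintf("unsupported encoding: '%s' is not a RIFF/WAVE file", path),
         call. = FALSE)
  }

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", size)
      fmt <- list(
        format    = sum(as.integer(body[1:2]) * c(1L, 256L)),
        channels  = sum(as.integer(body[3:4]) * c(1L, 256L)),
        rate      = sum(as.integer(body[5:8]) * c(1, 256, 65536, 16777216)),
        bits      = sum(as.integer(body[15:16]) * c(1L, 256L))
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      invisible(readBin(con, "raw", size))
    }
    if (size %% 2L == 1L) invisible(readBin(con, "raw", 1))  # chunk padding
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) {
    stop(sprintf("unsupported encoding: '%s' lacks fmt/data chunks", path),
         call. = FALSE)
  }

  if (fmt$format == 1L && fmt$bits == 16L) {
    x <- readBin(data_raw, "integer", n = length(data_raw) %/% 2L,
                 size = 2, signed = TRUE, endian = "little") / 32768
  } else if (fmt$format == 3L && fmt$bits == 32L) {
    x <- readBin(data_raw, "double", n = length(data_raw) %/% 4L,
                 size = 4, endian = "little")
  } else {
    stop(sprintf(
      "unsupported encoding: format tag %d / %d bits (need 16-bit PCM or 32-bit float)",
      fmt$format, fmt$bits
    ), call. = FALSE)
  }

  if (fmt$channels > 1L) {
    x <- colMeans(matrix(x, nrow = fmt$channels))
  }
  audio_signal(x, fmt$rate)
}

#' Write a mono audio signal to a WAV file
#'
#' Samples outside \[-1, 1\] are clipped at write time with a warning
#' (16-bit PCM saturates at full scale; float files are clipped identically
#' so the two depths stay interchangeable).
#'
#' @param signal A [audio_signal()].
#' @param path Destination file path; its directory must exist.
#' @param bit_depth `"16"` for 16-bit PCM or `"32f"` for 32-bit IEEE float.
#' @return `path`, invisibly.
#' @export
write_wav <- function(signal, path, bit_depth = c("16", "32f")) {
  stopifnot(inherits(signal, "ci_audio"))
  bit_depth <- match.arg(bit_depth)
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    stop(sprintf("destination directory does not exist: '%s'", dir), call. = FALSE)
  }
  x <- signal$samples
  if (length(x) && max(abs(x)) > 1) {
    warning("samples exceed [-1, 1]; clipping at full scale on write",
            call. = FALSE)
    x <- pmin(pmax(x, -1), 1)
  }

  if (bit_depth == "16") {
    fmt_tag <- 1L; bits <- 16L; bytes <- 2L
  } else {
    fmt_tag <- 3L; bits <- 32L; bytes <- 4L
  }
  n <- length(x)
  data_size <- n * bytes
  rate <- as.integer(round(signal$rate))

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt_tag, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")  # mono
  writeBin(rate, con, size = 4, endian = "little")
  writeBin(as.integer(rate * bytes), con, size = 4, endian = "little")
  writeBin(bytes, con, size = 2, endian = "little")
  writeBin(bits, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (bit_depth == "16") {
    # scale matches the reader's /32768; +1.0 saturates to 32767
    ints <- pmin(pmax(round(x * 32768), -32768), 32767)
    writeBin(as.integer(ints), con, size = 2, endian = "little")
  } else if (n) {
    writeBin(x, con, size = 4, endian = "little")
  }
  invisible(path)
}

# ---- rate and level utilities ---------------------------------------------

#' Resample an audio signal to a new rate
#'
#' Band-limited polyphase resampling (anti-alias FIR on downsampling) via
#' the rational factor closest to `target_rate / rate`. The vocoder path
#' uses this for its 44.1 kHz -> 16 kHz -> 44.1 kHz round trip.
#'
#' @param signal A [audio_signal()].
#' @param target_rate Target sampling rate in Hz (> 0).
#' @return A [audio_signal()] at `target_rate`.
#' @export
resample_audio <- function(signal, target_rate) {
  stopifnot(inherits(signal, "ci_audio"))
  if (!is.numeric(target_rate) || length(target_rate) != 1L ||
      !is.finite(target_rate) || target_rate <= 0) {
    stop("`target_rate` must be a single positive number (Hz)", call. = FALSE)
  }
  if (isTRUE(all.equal(target_rate, signal$rate))) {
    return(signal)
  }
  pq <- rational_approx(target_rate / signal$rate)
  y <- signal::resample(signal$samples, pq[1], pq[2])
  n_target <- round(length(signal$samples) * target_rate / signal$rate)
  # polyphase output may over/undershoot by a couple of samples at the tail
  if (length(y) >= n_target) {
    y <- y[seq_len(n_target)]
  } else {
    y <- c(y, numeric(n_target - length(y)))
  }
  audio_signal(y, target_rate)
}

# best small rational p/q for a ratio (continued-fraction expansion)
rational_approx <- function(r, max_den = 10000L, tol = 1e-9) {
  stopifnot(r > 0)
  a <- floor(r); p0 <- 1; q0 <- 0; p1 <- a; q1 <- 1
  frac <- r - a
  while (abs(p1 / q1 - r) > tol * r && q1 < max_den && frac > 1e-12) {
    r2 <- 1 / frac
    a <- floor(r2)
    frac <- r2 - a
    p2 <- a * p1 + p0; q2 <- a * q1 + q0
    if (q2 > max_den) break
    p0 <- p1; q0 <- q1; p1 <- p2; q1 <- q2
  }
  c(as.integer(p1), as.integer(q1))
}

#' Match the RMS level of a signal to a reference
#'
#' Applies the single global gain that makes the output RMS equal the
#' reference RMS. Every full processing chain ends with this against its
#' input, standardizing output level. A silent input is returned unchanged
#' (no gain can change its level); a silent reference is an error.
#'
#' @param signal A [audio_signal()] to rescale.
#' @param reference A [audio_signal()] whose RMS is the target.
#' @return A [audio_signal()] with the reference RMS.
#' @export
match_rms <- function(signal, reference) {
  stopifnot(inherits(signal, "ci_audio"), inherits(reference, "ci_audio"))
  r_ref <- audio_rms(reference)
  if (r_ref == 0) {
    stop("reference signal is silent (zero RMS)", call. = FALSE)
  }
  r_sig <- audio_rms(signal)
  if (r_sig == 0) {
    return(signal)  # documented all-zero passthrough
  }
  audio_signal(signal$samples * (r_ref / r_sig), signal$rate)
}
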