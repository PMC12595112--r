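# Fixtures are built in code at test time; no audio files ship with the
# package.

fix_sine <- function(freq = 440, duration = 0.5, rate = 44100) {
  generate_full_scale_sine(freq, duration, rate)
}

fix_noise <- function(n = 22050, rate = 44100, seed = 101, amp = 0.1) {
  withr::with_seed(seed, audio_signal(stats::rnorm(n) * amp, rate))
}

fix_sentence <- function(seed = 42, duration = 1.2) {
  generate_sentence(sentence_spec(duration = duration, seed = seed))
}

# raw WAV writer with arbitrary format fields, for exercising the reader's
# multichannel averaging and its unsupported-encoding error path
write_raw_wav <- function(path, samples_by_channel, rate = 44100,
                          bits = 16L, fmt_tag = 1L) {
  channels <- length(samples_by_channel)
  # column-major flatten of a channels x n matrix interleaves frames
  interleaved <- as.vector(do.call(rbind, samples_by_channel))
  bytes <- bits %/% 8L
  data_size <- length(interleaved) * bytes
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(as.integer(fmt_tag), con, size = 2, endian = "little")
  writeBin(as.integer(channels), con, size = 2, endian = "little")
  writeBin(as.integer(rate), con, size = 4, endian = "little")
  writeBin(as.integer(rate * bytes * channels), con, size = 4, endian = "little")
  writeBin(as.integer(bytes * channels), con, size = 2, endian = "little")
  writeBin(as.integer(bits), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (bits == 16L) {
    writeBin(as.integer(round(interleaved * 32767)), con, size = 2,
             endian = "little")
  } else if (bits == 8L) {
    writeBin(as.raw(round((interleaved + 1) * 127.5)), con)
  }
  invisible(path)
}

# total spectral energy of a signal inside [lo, hi] Hz (unnormalized)
band_energy <- function(signal, lo, hi) {
  n <- length(signal$samples)
  p <- Mod(stats::fft(signal$samples))^2
  f <- (seq_len(n) - 1) * signal$rate / n
  sum(p[f >= lo & f <= hi])
}

# total harmonic distortion of a near-sinusoid at f0 (harmonics 2-10)
measure_thd <- function(signal, f0) {
  sp <- spectrum_tbl(signal)
  fund <- max(sp$amplitude[abs(sp$freq - f0) < 5])
  harm <- vapply(2:10, function(k) {
    max(c(0, sp$amplitude[abs(sp$freq - k * f0) < 5]))
  }, 0)
  sqrt(sum(harm^2)) / fund
}

# independent top-k formulation: keep everything above the n-th largest
# value, then fill remaining slots among ties by lowest band index
oracle_top_k <- function(x, n) {
  out <- numeric(length(x))
  sorted <- sort(x, decreasing = TRUE)
  thr <- sorted[n]
  sure <- which(x > thr)
  ties <- which(x == thr)
  take <- c(sure, ties[seq_len(n - length(sure))])
  out[take] <- x[take]
  out
}
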