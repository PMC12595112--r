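test_that("the analysis table has 22 contiguous bands below 8 kHz", {
  tbl <- band_table()
  expect_equal(nrow(tbl), 22)
  expect_true(all(diff(tbl$lower_hz) > 0))
  expect_true(all(tbl$upper_hz > tbl$lower_hz))
  expect_equal(tbl$lower_hz[-1], tbl$upper_hz[-22])  # contiguous
  expect_gte(tbl$lower_hz[1], 100)
  expect_lte(tbl$upper_hz[22], 8000)
  expect_equal(attr(tbl, "processing_rate"), 16000)
})

test_that("FFT decomposition localizes tones and returns 22 envelopes", {
  tbl <- band_table()
  t <- (0:7999) / 16000
  tone <- audio_signal(sin(2 * pi * 1000 * t), 16000)
  env <- fft_decompose(tone, tbl)
  expect_equal(ncol(env), 22)
  expect_true(all(env >= 0))
  hit <- which.max(colMeans(env))
  expect_equal(hit, which(tbl$lower_hz <= 1000 & tbl$upper_hz > 1000))

  silence <- audio_signal(numeric(4000), 16000)
  expect_true(all(fft_decompose(silence, tbl) == 0))

  expect_error(fft_decompose(audio_signal(numeric(64), 16000), tbl),
               "shorter than one analysis frame")
  expect_error(fft_decompose(audio_signal(numeric(4000), 44100), tbl),
               "16000")
})

test_that("maxima selection keeps exactly the largest n per frame", {
  frame <- matrix(c(5, 3, 9, 1, rep(0, 18)), nrow = 1)
  out <- select_maxima(frame, 2)
  expect_equal(as.vector(out), c(5, 0, 9, rep(0, 19)))

  env <- matrix(withr::with_seed(4, stats::runif(50 * 22)), 50, 22)
  expect_identical(select_maxima(env, 22), env)
  one <- select_maxima(env, 1)
  expect_true(all(rowSums(one > 0) <= 1))

  expect_error(select_maxima(env, 0), "between 1 and 22")
  expect_error(select_maxima(env, 23), "between 1 and 22")
})

test_that("maxima selection matches an independent top-k oracle on 1000 frames", {
  env <- matrix(withr::with_seed(11, stats::runif(1000 * 22)), 1000, 22)
  # a share of exact ties and zeros to exercise tie-breaking
  env[withr::with_seed(12, sample(length(env), 2000))] <- 0.5
  env[withr::with_seed(13, sample(length(env), 2000))] <- 0
  for (n_sel in c(1, 4, 8, 21)) {
    got <- select_maxima(env, n_sel)
    want <- t(apply(env, 1, oracle_top_k, n = n_sel))
    expect_identical(unname(unclass(got)), want)
    # every retained value >= every zeroed value, per frame
    for (i in c(1, 500, 1000)) {
      kept <- got[i, got[i, ] > 0]
      dropped <- env[i, got[i, ] == 0]
      if (length(kept) && length(dropped)) {
        expect_gte(min(kept), max(dropped))
      }
    }
  }
})

test_that("synthesis honours silence, band placement, and noise seeding", {
  tbl <- band_table()
  env <- matrix(0, 100, 22)
  attr(env, "hop") <- 32L; attr(env, "frame_length") <- 128L
  expect_true(all(synthesize(env, tbl, "sine", "flat")$samples == 0))

  env7 <- env; env7[, 7] <- 1  # band 7 centered at 1000 Hz
  out <- synthesize(env7, tbl, "sine", "flat")
  expect_equal(out$rate, 16000)
  bin <- 16000 / length(out$samples)
  expect_lte(abs(dominant_frequency(out, 300, 3000) - tbl$center_hz[7]),
             bin + 1e-9)

  n1 <- synthesize(env7, tbl, "noise", "moderate", noise_seed = 5)
  n2 <- synthesize(env7, tbl, "noise", "moderate", noise_seed = 5)
  n3 <- synthesize(env7, tbl, "noise", "moderate", noise_seed = 6)
  expect_identical(n1$samples, n2$samples)
  expect_false(identical(n1$samples, n3$samples))
  expect_error(synthesize(env7, tbl, "noise", "moderate"), "noise_seed")
  expect_error(synthesize(env7[, 1:10], tbl), "columns")
})

test_that("narrow SOE noise bands carry less out-of-band energy than flat ones", {
  # Both orders share the band edges (the -3 dB points of a Butterworth
  # band-pass at any order), so spectral spread is compared as equivalent
  # noise bandwidth of the realized carrier-band response: narrower SOE =
  # steeper slopes = less energy leaking beyond the edges.
  tbl <- band_table()
  k <- 15
  f <- seq(10, 7990, by = 5)
  enb <- vapply(c(narrow = 4L, flat = 1L), function(ord) {
    sos <- cisim:::butter_sos(ord, c(tbl$lower_hz[k], tbl$upper_hz[k]),
                              16000, "pass")
    mag2 <- abs(cisim:::sos_response(sos, f, 16000))^2
    sum(mag2) * 5 / max(mag2)
  }, 0)
  expect_lt(enb[["narrow"]], enb[["flat"]])

  # the measured spectrum of the realized noise carriers agrees
  env <- matrix(0, 200, 22)
  attr(env, "hop") <- 32L; attr(env, "frame_length") <- 128L
  env[, k] <- 1
  out_band <- vapply(c("narrow", "flat"), function(soe) {
    s <- synthesize(env, tbl, "noise", soe, noise_seed = 1)
    1 - band_energy(s, tbl$lower_hz[k], tbl$upper_hz[k]) / band_energy(s, 0, 8000)
  }, 0)
  expect_lt(out_band[["narrow"]], out_band[["flat"]])
})

test_that("the FFT vocoder preserves the band-energy profile of speech", {
  sent <- fix_sentence(seed = 42, duration = 1.2)
  out <- fft_vocode(sent, stage_fft_vocoder(22, "sine", "flat"))
  expect_equal(out$rate, sent$rate)
  expect_lt(abs(duration(out) - duration(sent)) / duration(sent), 0.01)
  expect_equal(audio_rms(out), audio_rms(sent), tolerance = 1e-6)
  p_in <- band_energy_profile(resample_audio(sent, 16000))
  p_out <- band_energy_profile(resample_audio(out, 16000))
  expect_gte(stats::cor(p_in$energy, p_out$energy), 0.9)
})

test_that("n-of-m sparsity propagates through the full FFT pipeline", {
  sent <- fix_sentence(seed = 7, duration = 0.8)
  proc <- resample_audio(sent, 16000)
  env <- select_maxima(fft_decompose(proc), 1)
  expect_true(all(rowSums(env > 0) <= 1))
  out <- fft_vocode(sent, stage_fft_vocoder(1, "sine", "flat"))
  expect_length(out$samples, length(sent$samples))
})

test_that("the BP vocoder concentrates energy as its bank dictates", {
  tone <- generate_harmonic_tone(1000, 1, duration = 0.6)
  tbl <- band_table()
  out22 <- bp_vocode(tone, stage_bp_vocoder(22, "sine", "flat"))
  k <- which(tbl$lower_hz <= 1000 & tbl$upper_hz > 1000)
  bin <- tone$rate / length(tone$samples)
  expect_lte(abs(dominant_frequency(out22, 300, 3000) - tbl$center_hz[k]),
             bin + 1e-9)

  sent <- fix_sentence(seed = 9, duration = 0.8)
  out1 <- bp_vocode(sent, stage_bp_vocoder(1, "sine", "flat"))
  # single band: energy concentrated around the full-range center
  ctr <- (tbl$lower_hz[1] + tbl$upper_hz[22]) / 2
  inside <- band_energy(out1, ctr - 1500, ctr + 1500)
  total <- band_energy(out1, 0, 22050)
  expect_gt(inside / total, 0.5)

  d1 <- bp_vocode(sent, stage_bp_vocoder(8, "noise", "narrow", noise_seed = 3))
  d2 <- bp_vocode(sent, stage_bp_vocoder(8, "noise", "narrow", noise_seed = 3))
  expect_identical(d1$samples, d2$samples)
})

test_that("vocoder specs validate their ranges", {
  expect_error(stage_fft_vocoder(0), "between 1 and 22")
  expect_error(stage_fft_vocoder(23), "between 1 and 22")
  expect_error(stage_fft_vocoder(8, "noise"), "noise_seed")
  expect_error(stage_bp_vocoder(0), "between 1 and 22")
  expect_error(stage_bp_vocoder(5, "noise"), "noise_seed")
})
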