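test_that("an empty chain returns the input unchanged", {
  s <- fix_sine(440)
  expect_identical(apply_chain(s, parameter_set("empty")), s)
})

test_that("a single-stage chain equals direct application plus RMS match", {
  s <- fix_sentence(seed = 5, duration = 0.6)
  st <- stage_pass_filter("low", 4, cutoff_high = 2.0)
  via_chain <- apply_chain(s, parameter_set("lp", list(st)))
  direct <- match_rms(apply_stage(s, st), s)
  expect_equal(via_chain$samples, direct$samples, tolerance = 1e-12)
})

test_that("a failing stage aborts the chain naming its index", {
  s <- audio_signal(sin(2 * pi * 440 * (0:7999) / 16000), 16000)
  # comb requires 44.1 kHz, so it fails as stage 2 on a 16 kHz signal
  pset <- parameter_set("bad", list(
    stage_clip(2.0), stage_comb_filter(2100, 10)
  ))
  expect_error(apply_chain(s, pset), "stage 2")
})

test_that("chains are deterministic, including seeded noise carriers", {
  s <- fix_sentence(seed = 31, duration = 0.8)
  pset <- parameter_set("voc", list(
    stage_fft_vocoder(8, "noise", "moderate", noise_seed = 99)
  ))
  expect_identical(apply_chain(s, pset)$samples, apply_chain(s, pset)$samples)
})

test_that("parameter sets survive a serialization round trip", {
  for (pset in screening_catalog()) {
    f <- withr::local_tempfile(fileext = ".yaml")
    write_parameter_set(pset, f)
    back <- read_parameter_set(f)
    expect_equal(back, pset)
  }
  rec <- participant_catalog()
  for (pset in rec$parameter_set) {
    f <- withr::local_tempfile(fileext = ".yaml")
    write_parameter_set(pset, f)
    expect_equal(read_parameter_set(f), pset)
  }
})

test_that("a hand-edited preset file off the grid is rejected on read", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "id: bad", "stages:", "- stage: pass_filter", "  kind: low",
    "  order: 4", "  cutoff_high: 2.05"
  ), f)
  expect_error(read_parameter_set(f), "grid")
})

test_that("the screening catalog holds the ten described simulations", {
  sets <- screening_catalog()
  expect_length(sets, 10)
  expect_equal(vapply(sets, function(p) p$id, ""), as.character(1:10))
  kinds <- lapply(sets, function(p) vapply(p$stages, cisim:::stage_kind, ""))
  expect_true(any(vapply(kinds, function(k) "BP vocoder" %in% k, TRUE)))
  expect_true(any(vapply(kinds, function(k) "FFT vocoder (sine)" %in% k, TRUE)))
  expect_true(any(vapply(kinds, function(k) "FFT vocoder (noise)" %in% k, TRUE)))
  expect_equal(sum(vapply(kinds, function(k) "comb filter" %in% k, TRUE)), 2)

  # set 1 (band-pass) runs and changes a synthetic sentence
  s <- fix_sentence(seed = 17, duration = 0.6)
  out <- apply_chain(s, sets[[1]])
  expect_false(identical(out$samples, s$samples))
})

test_that("the participant catalog reproduces the described usage pattern", {
  rec <- participant_catalog()
  expect_equal(nrow(rec), 15)
  expect_equal(rec$participant_id, sprintf("#%d", 201:215))
  expect_equal(sum(rec$n_stages == 0), 2)
  expect_setequal(rec$participant_id[rec$n_stages == 0], c("#205", "#212"))
  expect_equal(max(rec$n_stages), 3)
  expect_equal(rec$participant_id[which.max(rec$n_stages)], "#203")

  kinds_per <- lapply(rec$parameter_set, function(p) {
    unique(vapply(p$stages, cisim:::stage_kind, ""))
  })
  count_kind <- function(k) sum(vapply(kinds_per, function(x) k %in% x, TRUE))
  expect_equal(count_kind("low-pass filter"), 4)
  expect_equal(count_kind("comb filter"), 4)
  # never required by any participant:
  expect_equal(count_kind("BP vocoder"), 0)
  expect_equal(count_kind("frequency shift"), 0)
  expect_equal(count_kind("overmodulation"), 0)

  # all scores on the rating scale
  for (col in paste0("similarity_s", 1:3)) {
    expect_true(all(vapply(rec[[col]], function(v) {
      isTRUE(tryCatch(validate_score(v) == v, error = function(e) FALSE))
    }, TRUE)))
  }
})

test_that("every participant chain replays on a synthetic sentence", {
  s <- fix_sentence(seed = 23, duration = 0.6)
  rec <- participant_catalog()
  for (i in seq_len(nrow(rec))) {
    out <- apply_chain(s, rec$parameter_set[[i]])
    expect_true(all(is.finite(out$samples)))
    expect_length(out$samples, length(s$samples))
  }
})

test_that("catalog statistics match the published aggregates", {
  sm <- catalog_summary(participant_catalog())
  expect_equal(round(sm$stages$mean_stages, 1), 1.4)
  expect_equal(sm$stages$max_stages, 3)
  sc <- sm$scores
  expect_equal(round(sc$mean[sc$sentence == 1], 1), 9.7)
  expect_equal(sc$median[sc$sentence == 1], 10.0)
  expect_equal(round(sc$mean[sc$sentence == 2], 1), 8.4)
  expect_equal(round(sc$mean[sc$sentence == 3], 1), 8.9)
  expect_equal(sc$n_at_max[sc$sentence == 1], 10)
  expect_error(catalog_summary(tibble::tibble()), "nonempty")
})

test_that("tidiers expose chains and summaries as tibbles", {
  rec <- participant_catalog()
  td <- tidy(rec$parameter_set[[3]])  # #203, three stages
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 3)
  expect_equal(td$position, 1:3)

  sm <- catalog_summary(rec)
  g <- glance(sm)
  expect_equal(g$n_records, 15)
  expect_equal(round(g$prop_at_max, 2), 0.67)
  expect_equal(nrow(tidy(sm)), 3)
})

test_that("packaged catalog files match their recorded checksums", {
  # transcription-audit guard: any edit to the shipped tables must be
  # deliberate and re-recorded here
  sums <- tools::md5sum(c(
    system.file("extdata", "screening-sets-reconstructed.yaml", package = "cisim"),
    system.file("extdata", "participant-records-reconstructed.yaml", package = "cisim"),
    system.file("extdata", "ace-band-table.csv", package = "cisim")
  ))
  expect_equal(unname(sums), c(
    "1093a417f3c99896e49c314c61b95de1",
    "ab30296868570e051d2b64b54003534e",
    "210b5d9df1f3ef233d2305643e7f74f8"
  ))
})
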