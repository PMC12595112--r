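#' Validate a similarity score
#'
#' The rating scale runs from 1 (no similarity) to 10 (signals are
#' identical) in steps of 0.5 — exactly 19 admissible values.
#'
#' @param raw A number.
#' @return The validated score (invisibly the same number).
#' @examples
#' validate_score(5.5)
#' @export
validate_score <- function(raw) {
  if (!is.numeric(raw) || length(raw) != 1L || !is.finite(raw)) {
    stop("a similarity score must be a single number", call. = FALSE)
  }
  if (raw < 1 || raw > 10 || abs(raw * 2 - round(raw * 2)) > 1e-9) {
    stop(sprintf(
      "%g is not on the similarity scale (1 to 10 in steps of 0.5)", raw
    ), call. = FALSE)
  }
  raw
}

#' Build the screening-experiment stimulus battery
#'
#' Applies each of the 10 parameter sets to each of the 10 sentences:
#' 10 blocks (one per sentence) of 10 simulations, 100 stimuli in all.
#' Within each block the presentation order is a seeded random permutation
#' of the presets; block order is fixed (sentence 1 to 10). One global seed
#' deterministically derives a per-block sub-seed, so a session is
#' bit-reproducible, including noise-carrier stages whose seeds live in the
#' preset definitions.
#'
#' @param sentences List of exactly 10 [audio_signal()]s.
#' @param presets List of exactly 10 [parameter_set()]s
#'   (default [screening_catalog()]).
#' @param seed Integer master seed for the presentation orders.
#' @param out_dir Directory to write the 100 processed WAV files and the
#'   manifest into; created if missing. `NULL` skips writing audio and
#'   returns the manifest only.
#' @param bit_depth Passed to [write_wav()].
#' @return The manifest: a tibble of class `ci_battery_manifest` with one
#'   row per stimulus (`block`, `sentence_id`, `preset_id`, `position`,
#'   `file`) and the seed as an attribute. Also written to
#'   `out_dir/manifest.csv` when audio is written.
#' @export
build_battery <- function(sentences, presets = screening_catalog(), seed,
                          out_dir = NULL, bit_depth = "16") {
  if (!is.list(sentences) || length(sentences) != 10 ||
      !all(vapply(sentences, inherits, TRUE, "ci_audio"))) {
    stop("`sentences` must be a list of exactly 10 audio signals", call. = FALSE)
  }
  if (!is.list(presets) || length(presets) != 10 ||
      !all(vapply(presets, inherits, TRUE, "ci_parameter_set"))) {
    stop("`presets` must be a list of exactly 10 parameter sets", call. = FALSE)
  }
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L) {
    stop("`seed` is mandatory (integer)", call. = FALSE)
  }
  seed <- as.integer(seed)
  write_audio <- !is.null(out_dir)
  if (write_audio && !dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop(sprintf("cannot create output directory '%s'", out_dir),
                  call. = FALSE)
  }

  preset_ids <- vapply(presets, function(p) p$id, "")
  rows <- vector("list", 100L)
  k <- 0L
  for (b in seq_len(10)) {
    # per-block sub-seed derived from the master seed, kept below 2^31
    block_seed <- (seed %% 1000000L) * 1000L + b
    perm <- with_preserved_rng(block_seed, sample.int(10L))
    # perm[j] = preset presented at position j of this block
    for (j in seq_len(10)) {
      p_idx <- perm[j]
      k <- k + 1L
      file <- if (write_audio) {
        file.path(out_dir, sprintf("block%02d_pos%02d_set%s.wav",
                                   b, j, preset_ids[p_idx]))
      } else {
        NA_character_
      }
      if (write_audio) {
        stim <- apply_chain(sentences[[b]], presets[[p_idx]])
        # RMS matching can push high-crest-factor stimuli past full scale;
        # a per-stimulus safety gain avoids saturation distortion on disk
        # (presentation loudness was set subjectively in the study anyway)
        peak <- if (length(stim$samples)) max(abs(stim$samples)) else 0
        if (peak > 0.99) {
          stim <- audio_signal(stim$samples * (0.99 / peak), stim$rate)
        }
        write_wav(stim, file, bit_depth = bit_depth)
      }
      rows[[k]] <- tibble::tibble(
        block = b, sentence_id = b, preset_id = preset_ids[p_idx],
        position = j, file = file
      )
    }
  }
  manifest <- dplyr::bind_rows(rows)
  attr(manifest, "seed") <- seed
  class(manifest) <- c("ci_battery_manifest", class(manifest))
  if (write_audio) {
    utils::write.csv(cbind(manifest, seed = seed),
                     file.path(out_dir, "manifest.csv"), row.names = FALSE)
  }
  manifest
}
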