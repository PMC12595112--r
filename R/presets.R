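#' Ordered chain of processing stages
#'
#' A parameter set is what the study called one "simulation": an ordered,
#' possibly empty, list of validated stage specifications applied in listed
#' order. The screening and participant catalogs are lists of these.
#'
#' @param id Label for the set.
#' @param stages List of stage specifications (`stage_*()` constructors).
#' @return An object of class `ci_parameter_set`.
#' @examples
#' parameter_set("lp-demo", list(stage_pass_filter("low", 4, cutoff_high = 2)))
#' @export
parameter_set <- function(id, stages = list()) {
  if (!is.list(stages) || (length(stages) && !all(vapply(stages, inherits, TRUE, "ci_stage")))) {
    stop("`stages` must be a list of stage specifications", call. = FALSE)
  }
  structure(list(id = as.character(id), stages = stages),
            class = "ci_parameter_set")
}

#' @export
print.ci_parameter_set <- function(x, ...) {
  cat(sprintf("<ci_parameter_set> '%s': %d stage(s)\n", x$id, length(x$stages)))
  for (i in seq_along(x$stages)) {
    cat(sprintf("  %d. %s\n", i, stage_label(x$stages[[i]])))
  }
  invisible(x)
}

# one-line human-readable description of a stage (logs, print, tidy)
stage_label <- function(stage) {
  switch(class(stage)[1],
    ci_stage_pass_filter = switch(stage$kind,
      low  = sprintf("low-pass, order %d, %.1f kHz", stage$order, stage$cutoff_high),
      high = sprintf("high-pass, order %d, %.1f kHz", stage$order, stage$cutoff_low),
      band = sprintf("band-pass, order %d, %.1f-%.1f kHz", stage$order,
                     stage$cutoff_low, stage$cutoff_high)),
    ci_stage_comb_filter = sprintf("comb, f0 %g Hz, q %g", stage$f0, stage$q),
    ci_stage_pitch_shift = sprintf("pitch shift, %+d semitones", stage$semitones),
    ci_stage_frequency_shift = sprintf("frequency shift, %+g Hz", stage$delta_f),
    ci_stage_clip = sprintf("overmodulation, factor %.1f", stage$factor),
    ci_stage_fft_vocoder = sprintf("FFT vocoder, %d-of-22, %s carrier, SOE %s",
                                   stage$n_selected, stage$carrier, stage$soe),
    ci_stage_bp_vocoder = sprintf("BP vocoder, %d bands, %s carrier, SOE %s",
                                  stage$n_bands, stage$carrier, stage$soe),
    "unknown stage"
  )
}

# coarse modification kind, FFT carriers counted as distinct kinds
stage_kind <- function(stage) {
  switch(class(stage)[1],
    ci_stage_pass_filter = paste0(stage$kind, switch(stage$kind,
      low = "-pass filter", high = "-pass filter", band = "-pass filter")),
    ci_stage_comb_filter = "comb filter",
    ci_stage_pitch_shift = "pitch shift",
    ci_stage_frequency_shift = "frequency shift",
    ci_stage_clip = "overmodulation",
    ci_stage_fft_vocoder = sprintf("FFT vocoder (%s)", stage$carrier),
    ci_stage_bp_vocoder = "BP vocoder",
    "unknown"
  )
}

#' Apply a parameter set to an audio signal
#'
#' Runs every stage in listed order, then matches the output RMS to the
#' input (the study set presentation loudness subjectively; the library
#' standardizes level instead). An empty chain returns the input unchanged.
#' A failing stage aborts with the stage index in the error.
#'
#' @param signal A [audio_signal()].
#' @param pset A [parameter_set()].
#' @param verbose If `TRUE`, log each applied stage to standard error.
#' @return The processed [audio_signal()].
#' @export
apply_chain <- function(signal, pset, verbose = FALSE) {
  stopifnot(inherits(signal, "ci_audio"), inherits(pset, "ci_parameter_set"))
  if (!length(pset$stages)) return(signal)
  out <- signal
  for (i in seq_along(pset$stages)) {
    stage <- pset$stages[[i]]
    if (verbose) message(sprintf("[%s] stage %d: %s", pset$id, i, stage_label(stage)))
    out <- tryCatch(
      apply_stage(out, stage),
      error = function(e) stop(sprintf("stage %d (%s) failed: %s",
                                       i, class(stage)[1], conditionMessage(e)),
                               call. = FALSE)
    )
  }
  match_rms(out, signal)
}

# ---- serialization ---------------------------------------------------------

stage_to_list <- function(stage) {
  type <- sub("^ci_stage_", "", class(stage)[1])
  c(list(stage = type), Filter(Negate(is.null), unclass(stage)))
}

stage_from_list <- function(lst) {
  type <- lst$stage
  lst$stage <- NULL
  fn <- switch(type,
    pass_filter = stage_pass_filter, comb_filter = stage_comb_filter,
    pitch_shift = stage_pitch_shift, frequency_shift = stage_frequency_shift,
    clip = stage_clip, fft_vocoder = stage_fft_vocoder,
    bp_vocoder = stage_bp_vocoder,
    stop(sprintf("unknown stage type '%s'", type), call. = FALSE)
  )
  do.call(fn, lst)
}

parameter_set_to_list <- function(pset) {
  list(id = pset$id, stages = lapply(pset$stages, stage_to_list))
}

parameter_set_from_list <- function(lst) {
  parameter_set(lst$id, lapply(lst$stages, stage_from_list))
}

#' Read/write parameter-set files
#'
#' Parameter sets are stored as human-readable YAML: an `id` and an ordered
#' list of typed stage records whose fields are re-validated on read, so a
#' hand-edited file off the parameter grid is rejected.
#'
#' @param pset A [parameter_set()].
#' @param path File path.
#' @return `read_parameter_set()` returns a [parameter_set()];
#'   `write_parameter_set()` returns `path` invisibly.
#' @export
write_parameter_set <- function(pset, path) {
  stopifnot(inherits(pset, "ci_parameter_set"))
  yaml::write_yaml(parameter_set_to_list(pset), path)
  invisible(path)
}

#' @rdname write_parameter_set
#' @export
read_parameter_set <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path), call. = FALSE)
  parameter_set_from_list(yaml::read_yaml(path))
}

# ---- packaged catalogs -----------------------------------------------------

the_catalogs <- new.env(parent = emptyenv())

catalog_path <- function(file) {
  system.file("extdata", file, package = "cisim")
}

#' The 10 screening parameter sets
#'
#' The ten "simulation" chains of the screening experiment: mild pass
#' filters, pitch/frequency shift + overmodulation combinations, comb
#' filters, the BP vocoder, and the FFT vocoders with sine and noise
#' carriers. The published table's cell values are not machine-readable in
#' the source text, so the shipped file
#' (`extdata/screening-sets-reconstructed.yaml`) is a reconstruction
#' consistent with the described set kinds; it is data, not code, and can be
#' corrected without touching the package.
#'
#' @return A list of 10 [parameter_set()]s with ids `"1"` to `"10"`.
#' @export
screening_catalog <- function() {
  if (is.null(the_catalogs$screening)) {
    raw <- yaml::read_yaml(catalog_path("screening-sets-reconstructed.yaml"))
    the_catalogs$screening <- lapply(raw$sets, parameter_set_from_list)
  }
  the_catalogs$screening
}

#' The 15 participant-optimized parameter sets
#'
#' One record per study participant (#201-#215): the optimized chain plus
#' the similarity scores the participant gave for the optimization sentence
#' (s1) and the two transfer sentences (s2, s3), and the participant's final
#' comment. Reconstructed data (see [screening_catalog()] for why), shipped
#' as `extdata/participant-records-reconstructed.yaml`; the reconstruction
#' reproduces every aggregate reported for the original table.
#'
#' @return A tibble with columns `participant_id`, `parameter_set`
#'   (list-column of [parameter_set()]), `n_stages`, `similarity_s1`,
#'   `similarity_s2`, `similarity_s3`, `final_comment`.
#' @export
participant_catalog <- function() {
  if (is.null(the_catalogs$participants)) {
    raw <- yaml::read_yaml(catalog_path("participant-records-reconstructed.yaml"))
    recs <- purrr::map(raw$records, function(r) {
      pset <- parameter_set(r$participant_id, lapply(r$stages, stage_from_list))
      for (s in c(r$similarity_s1, r$similarity_s2, r$similarity_s3)) {
        validate_score(s)
      }
      tibble::tibble(
        participant_id = r$participant_id,
        parameter_set = list(pset),
        n_stages = length(pset$stages),
        similarity_s1 = r$similarity_s1,
        similarity_s2 = r$similarity_s2,
        similarity_s3 = r$similarity_s3,
        final_comment = r$final_comment
      )
    })
    the_catalogs$participants <- dplyr::bind_rows(recs)
  }
  the_catalogs$participants
}

#' Summarize a participant catalog
#'
#' Stage-usage counts (how many participants used each modification kind),
#' per-sentence similarity statistics (mean, sample SD, median, number of
#' records at the scale maximum 10.0), and modification-count statistics.
#'
#' @param records A tibble as returned by [participant_catalog()].
#' @return An object of class `ci_catalog_summary` with elements
#'   `usage`, `scores`, `stages` (tibbles) and `n_records`.
#' @export
catalog_summary <- function(records = participant_catalog()) {
  if (!is.data.frame(records) || nrow(records) == 0) {
    stop("`records` must be a nonempty participant-record tibble", call. = FALSE)
  }
  needed <- c("participant_id", "parameter_set",
              paste0("similarity_s", 1:3))
  if (!all(needed %in% names(records))) {
    stop("`records` lacks participant-catalog columns", call. = FALSE)
  }

  usage <- purrr::map_dfr(seq_len(nrow(records)), function(i) {
    kinds <- unique(vapply(records$parameter_set[[i]]$stages, stage_kind, ""))
    tibble::tibble(participant_id = records$participant_id[i], kind = kinds)
  }) |>
    dplyr::count(.data$kind, name = "n_participants") |>
    dplyr::arrange(dplyr::desc(.data$n_participants), .data$kind)

  n_stages <- vapply(records$parameter_set, function(p) length(p$stages), 0L)
  stages <- tibble::tibble(
    mean_stages = mean(n_stages),
    sd_stages = stats::sd(n_stages),
    median_stages = stats::median(n_stages),
    max_stages = max(n_stages),
    n_zero = sum(n_stages == 0)
  )

  scores <- tidyr::pivot_longer(
    records[, c("participant_id", paste0("similarity_s", 1:3))],
    dplyr::starts_with("similarity"),
    names_to = "sentence", names_prefix = "similarity_s",
    values_to = "score"
  ) |>
    dplyr::mutate(sentence = as.integer(.data$sentence)) |>
    dplyr::group_by(.data$sentence) |>
    dplyr::summarise(
      mean = mean(.data$score),
      sd = stats::sd(.data$score),
      median = stats::median(.data$score),
      n_at_max = sum(.data$score == 10),
      .groups = "drop"
    )

  structure(
    list(usage = usage, scores = scores, stages = stages,
         n_records = nrow(records)),
    class = "ci_catalog_summary"
  )
}

#' @export
print.ci_catalog_summary <- function(x, ...) {
  cat(sprintf("<ci_catalog_summary> %d participant records\n", x$n_records))
  cat(sprintf("modifications per record: mean %.1f (SD %.1f), median %g, max %d; %d records unmodified\n",
              x$stages$mean_stages, x$stages$sd_stages, x$stages$median_stages,
              x$stages$max_stages, x$stages$n_zero))
  cat("stage usage (participants per kind):\n")
  for (i in seq_len(nrow(x$usage))) {
    cat(sprintf("  %-20s %d\n", x$usage$kind[i], x$usage$n_participants[i]))
  }
  cat("similarity scores:\n")
  for (i in seq_len(nrow(x$scores))) {
    cat(sprintf("  sentence %d: mean %.1f (SD %.1f), median %.1f, %d/%d at 10.0\n",
                x$scores$sentence[i], x$scores$mean[i], x$scores$sd[i],
                x$scores$median[i], x$scores$n_at_max[i], x$n_records))
  }
  invisible(x)
}
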