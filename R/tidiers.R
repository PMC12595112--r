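#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a parameter set into a stage table
#'
#' @param x A [parameter_set()].
#' @param ... Unused.
#' @return A tibble with one row per stage: `position`, `stage` (type),
#'   `kind` (modification kind) and `label` (human-readable parameters).
#' @method tidy ci_parameter_set
#' @export
tidy.ci_parameter_set <- function(x, ...) {
  if (!length(x$stages)) {
    return(tibble::tibble(position = integer(), stage = character(),
                          kind = character(), label = character()))
  }
  tibble::tibble(
    position = seq_along(x$stages),
    stage = vapply(x$stages, function(s) sub("^ci_stage_", "", class(s)[1]), ""),
    kind = vapply(x$stages, stage_kind, ""),
    label = vapply(x$stages, stage_label, "")
  )
}

#' Tidy / glance methods for catalog summaries
#'
#' `tidy()` returns the per-sentence score statistics; `glance()` a one-row
#' overview of the catalog.
#'
#' @param x A [catalog_summary()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy ci_catalog_summary
#' @export
tidy.ci_catalog_summary <- function(x, ...) {
  x$scores
}

#' @rdname tidy.ci_catalog_summary
#' @method glance ci_catalog_summary
#' @export
glance.ci_catalog_summary <- function(x, ...) {
  tibble::tibble(
    n_records = x$n_records,
    mean_stages = x$stages$mean_stages,
    sd_stages = x$stages$sd_stages,
    max_stages = x$stages$max_stages,
    n_unmodified = x$stages$n_zero,
    s1_mean = x$scores$mean[x$scores$sentence == 1],
    s1_median = x$scores$median[x$scores$sentence == 1],
    s2_mean = x$scores$mean[x$scores$sentence == 2],
    s3_mean = x$scores$mean[x$scores$sentence == 3],
    prop_at_max = x$scores$n_at_max[x$scores$sentence == 1] / x$n_records
  )
}

#' One-row summary of an audio signal
#'
#' @param x A [audio_signal()].
#' @param ... Unused.
#' @return A tibble with `n_samples`, `rate`, `duration`, `peak`, `rms`.
#' @method glance ci_audio
#' @export
glance.ci_audio <- function(x, ...) {
  tibble::tibble(
    n_samples = length(x$samples),
    rate = x$rate,
    duration = duration(x),
    peak = if (length(x$samples)) max(abs(x$samples)) else 0,
    rms = audio_rms(x)
  )
}
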