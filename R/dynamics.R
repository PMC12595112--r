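#' Overmodulation/clipping stage
#'
#' Multiplies the signal by `factor` and cuts it off at the input's own peak
#' amplitude, so `factor = 1.0` is an exact identity at any input level and
#' `factor = 20.0` is very strong clipping. The grid is 1.0-20.0 in steps
#' of 0.1.
#'
#' @param factor Gain before clipping, 1.0-20.0 on the 0.1 grid.
#' @return A stage specification (class `ci_stage_clip`).
#' @export
stage_clip <- function(factor) {
  if (!is.numeric(factor) || length(factor) != 1L || !is.finite(factor)) {
    stop("`factor` must be a single number", call. = FALSE)
  }
  if (factor < 1 || factor > 20) {
    stop("`factor` must lie in [1, 20]", call. = FALSE)
  }
  if (abs(factor * 10 - round(factor * 10)) > 1e-9) {
    stop(sprintf("`factor` = %g is off the 0.1 grid", factor), call. = FALSE)
  }
  structure(list(factor = as.double(factor)),
            class = c("ci_stage_clip", "ci_stage"))
}

#' @rdname apply_stage
#' @export
apply_stage.ci_stage_clip <- function(signal, stage, ...) {
  x <- signal$samples
  if (!length(x)) return(signal)
  bound <- max(abs(x))    # clip at the input's own peak, not full scale
  audio_signal(pmin(pmax(stage$factor * x, -bound), bound), signal$rate)
}
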