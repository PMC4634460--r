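#' Construct a PPG record
#'
#' A `ppg_record` bundles a single-channel fingertip photoplethysmogram with
#' its sampling rate and study metadata. Records are the unit every other
#' function operates on: one record is one 20-s measurement of one subject at
#' one protocol stage (before exercise `BE`, or after exercise `E1`/`E2`/`E3`).
#'
#' @param samples Numeric vector of signal amplitudes (arbitrary units).
#' @param fs Sampling rate in Hz. Must be positive.
#' @param subject_id Subject identifier string.
#' @param stage Stage label, one of `"BE"`, `"E1"`, `"E2"`, `"E3"`.
#'
#' @return An object of class `ppg_record`: a list with elements `samples`,
#'   `fs`, `subject_id`, `stage` and `n_samples`.
#' @export
#' @examples
#' r <- ppg_record(sin(2 * pi * 1.2 * seq(0, 5, by = 1 / 100)), fs = 100)
#' r
ppg_record <- function(samples, fs, subject_id = "S01", stage = "BE") {
  if (!is.numeric(samples) || length(samples) < 1L) {
    stop("`samples` must be a non-empty numeric vector", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("`fs` must be a single positive number", call. = FALSE)
  }
  stage <- match.arg(stage, ppg_stages())
  structure(
    list(samples = as.numeric(samples), fs = as.numeric(fs),
         subject_id = as.character(subject_id), stage = stage,
         n_samples = length(samples)),
    class = "ppg_record"
  )
}

#' Protocol stage labels
#'
#' @return Character vector `c("BE", "E1", "E2", "E3")`: one resting baseline
#'   and three post-exercise measurements.
#' @export
ppg_stages <- function() c("BE", "E1", "E2", "E3")

#' @export
print.ppg_record <- function(x, ...) {
  cat(sprintf("<ppg_record> subject %s, stage %s: %d samples @ %.6g Hz (%.2f s)\n",
              x$subject_id, x$stage, x$n_samples, x$fs, x$n_samples / x$fs))
  invisible(x)
}

#' @export
length.ppg_record <- function(x) x$n_samples
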