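# Inclusive 0-based range sum of squares: S(x:y)^2 with both endpoints kept.
seg_sq_sum <- function(signal, from0, to0) {
  sum(signal[(from0 + 1L):(to0 + 1L)]^2)
}

#' Energy of the ab area (f1)
#'
#' Sum over beats of the squared signal on the inclusive index range from
#' each a wave to its b wave. Energies are in squared amplitude units summed
#' over samples; they scale with recording length by construction.
#'
#' @param signal Numeric vector (filtered PPG or APG).
#' @param fiducials A [fiducial_set()] whose indices lie within `signal`.
#' @return Non-negative scalar. An empty fiducial set gives 0 with a warning.
#' @export
#' @examples
#' energy_ab(c(1, 2, 3, 4, 5), fiducial_set(a = 0, b = 2))  # 1 + 4 + 9
energy_ab <- function(signal, fiducials) {
  stopifnot(inherits(fiducials, "fiducial_set"))
  check_fid_range(signal, fiducials)
  if (length(fiducials$b) == 0L) {
    warning("no complete beats; ab energy is 0", call. = FALSE)
    return(0)
  }
  sum(vapply(seq_along(fiducials$b), function(n) {
    seg_sq_sum(signal, fiducials$a[n], fiducials$b[n])
  }, numeric(1)))
}

#' Energy of the aa area (f2)
#'
#' Sum over consecutive beat pairs of the squared signal on the inclusive
#' range from each a wave to the next. This is the headline heat-stress
#' feature: it tracks the pulse energy of the whole beat.
#'
#' @inheritParams energy_ab
#' @return Non-negative scalar.
#' @export
#' @examples
#' energy_aa(c(1, 2, 3, 4, 5), fiducial_set(a = c(0, 4), b = 2))  # 55
energy_aa <- function(signal, fiducials) {
  stopifnot(inherits(fiducials, "fiducial_set"))
  if (fiducials$n_beats < 2L) stop("aa energy needs at least 2 a waves", call. = FALSE)
  check_fid_range(signal, fiducials)
  a <- fiducials$a
  sum(vapply(seq_len(length(a) - 1L), function(n) {
    seg_sq_sum(signal, a[n], a[n + 1L])
  }, numeric(1)))
}

#' Energy of the ba area (f3)
#'
#' Sum over beats of the squared signal on the inclusive range from each
#' b wave to the next beat's a wave.
#'
#' @inheritParams energy_ab
#' @return Non-negative scalar.
#' @export
#' @examples
#' energy_ba(c(1, 2, 3, 4, 5), fiducial_set(a = c(0, 4), b = 2))  # 9 + 16 + 25
energy_ba <- function(signal, fiducials) {
  stopifnot(inherits(fiducials, "fiducial_set"))
  if (fiducials$n_beats < 2L) stop("ba energy needs at least 2 a waves", call. = FALSE)
  check_fid_range(signal, fiducials)
  k <- min(fiducials$n_beats - 1L, length(fiducials$b))
  sum(vapply(seq_len(k), function(n) {
    seg_sq_sum(signal, fiducials$b[n], fiducials$a[n + 1L])
  }, numeric(1)))
}

check_fid_range <- function(signal, fiducials) {
  idx <- c(fiducials$a, fiducials$b)
  if (length(idx) && max(idx) >= length(signal)) {
    stop("fiducial indices outside the signal", call. = FALSE)
  }
  invisible(TRUE)
}

#' Amplitude, ratio and slope features (f4--f7)
#'
#' Per-beat values aggregated to one record value by the arithmetic mean
#' over beats: the signal amplitude at the b wave (f4), at the a wave (f5),
#' their ratio b/a (f6), and the chord slope between them (f7, amplitude
#' units per sample). Beats where the a-wave amplitude is exactly zero are
#' excluded from the ratio mean with a warning.
#'
#' @inheritParams energy_ab
#' @return One-row tibble with columns `amp_b`, `amp_a`, `ratio_ba`,
#'   `slope_ab`.
#' @export
#' @examples
#' s <- numeric(60); s[11] <- -1.8; s[51] <- -1.2
#' amplitude_features(s, fiducial_set(a = 10, b = 50))
amplitude_features <- function(signal, fiducials) {
  stopifnot(inherits(fiducials, "fiducial_set"))
  if (length(fiducials$b) < 1L) stop("amplitude features need at least one complete beat", call. = FALSE)
  check_fid_range(signal, fiducials)
  k <- length(fiducials$b)
  sa <- signal[fiducials$a[seq_len(k)] + 1L]
  sb <- signal[fiducials$b[seq_len(k)] + 1L]
  gap <- fiducials$b[seq_len(k)] - fiducials$a[seq_len(k)]
  ok <- sa != 0
  if (!all(ok)) {
    warning(sprintf("%d beat(s) with zero a-wave amplitude excluded from the b/a ratio",
                    sum(!ok)), call. = FALSE)
  }
  tibble::tibble(
    amp_b = mean(sb),
    amp_a = mean(sa),
    ratio_ba = if (any(ok)) mean(sb[ok] / sa[ok]) else NA_real_,
    slope_ab = mean((sb - sa) / gap)
  )
}

#' RMSSD of the aa interval series
#'
#' Root mean square of successive differences of the beat-to-beat (aa)
#' intervals, in seconds -- the standard short-term heart-rate-variability
#' index of parasympathetic activity. `method = "literal"` instead returns
#' the root of the mean squared interval itself (a reading occasionally
#' implied by loose wording in the applied literature); it is exposed for
#' sensitivity analysis only.
#'
#' @param intervals aa intervals in samples (from [aa_intervals()]).
#' @param fs Sampling rate in Hz, used to convert intervals to seconds.
#' @param method `"diff"` (successive differences, default) or `"literal"`.
#' @return RMSSD in seconds, non-negative.
#' @export
#' @examples
#' rmssd(c(0.7, 0.9, 0.7, 0.9) * 100, fs = 100)  # 0.2
rmssd <- function(intervals, fs, method = c("diff", "literal")) {
  method <- match.arg(method)
  if (any(intervals <= 0)) stop("aa intervals must be positive", call. = FALSE)
  sec <- intervals / fs
  if (method == "literal") {
    if (length(sec) < 1L) stop("need at least 1 interval", call. = FALSE)
    return(sqrt(mean(sec^2)))
  }
  if (length(sec) < 2L) stop("need at least 2 intervals for successive differences", call. = FALSE)
  sqrt(mean(diff(sec)^2))
}

#' Extract the full feature vector of one record
#'
#' Computes the 14 time-domain features -- f1--f7 on the filtered PPG and on
#' the APG, using the same a/b index arrays -- plus the RMSSD of the aa
#' intervals. With a single beat the pairwise quantities (aa/ba energies,
#' RMSSD) are undefined and returned as `NA` with a warning.
#'
#' @param processed A [process_signal()] result.
#' @param fiducials A [fiducial_set()] on the same record.
#' @param rmssd_method Passed to [rmssd()].
#' @return One-row tibble: the 14 columns of [ppg_feature_names()], `rmssd`,
#'   and `n_beats_used`.
#' @export
#' @examples
#' rec <- generate_record(heat_stress_stages()$BE, seed = 3)
#' p <- process_signal(rec$record)
#' extract_features(p, rec$fiducials)
extract_features <- function(processed, fiducials, rmssd_method = "diff") {
  stopifnot(inherits(processed, "ppg_processed"), inherits(fiducials, "fiducial_set"))
  one <- function(signal) {
    amp <- amplitude_features(signal, fiducials)
    tibble::tibble(
      energy_ab = energy_ab(signal, fiducials),
      energy_aa = if (fiducials$n_beats >= 2L) energy_aa(signal, fiducials) else NA_real_,
      energy_ba = if (fiducials$n_beats >= 2L) energy_ba(signal, fiducials) else NA_real_,
      amp_b = amp$amp_b, amp_a = amp$amp_a,
      ratio_ba = amp$ratio_ba, slope_ab = amp$slope_ab
    )
  }
  if (fiducials$n_beats < 2L) {
    warning("single-beat record: aa/ba energies and RMSSD are NA", call. = FALSE)
  }
  ppg <- one(processed$ppg_filtered)
  apg <- one(processed$apg)
  names(ppg) <- paste0(names(ppg), "_ppg")
  names(apg) <- paste0(names(apg), "_apg")
  rm_val <- if (fiducials$n_beats >= 3L) {
    rmssd(aa_intervals(fiducials), processed$fs, method = rmssd_method)
  } else {
    NA_real_
  }
  dplyr::bind_cols(ppg, apg,
                   tibble::tibble(rmssd = rm_val, n_beats_used = fiducials$n_beats))
}

#' Extract features for every record of a cohort
#'
#' Maps [process_signal()] + [extract_features()] over a cohort tibble (as
#' produced by [generate_cohort()] or [read_cohort()]), returning the
#' feature matrix consumed by [screen_features()] and [classify_features()].
#'
#' @param cohort Tibble with columns `subject_id`, `stage`, `record`,
#'   `fiducials`.
#' @param low,high,order Filter design, see [bandpass_filter()].
#' @param rmssd_method Passed to [rmssd()].
#' @return Tibble: `subject_id`, `stage`, the 14 feature columns, `rmssd`,
#'   `n_beats_used`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_subjects = 2, seed = 5))
#' extract_cohort_features(cohort)
extract_cohort_features <- function(cohort, low = 0.5, high = 7, order = 2,
                                    rmssd_method = "diff") {
  stopifnot(all(c("subject_id", "stage", "record", "fiducials") %in% names(cohort)))
  feats <- purrr::map2(cohort$record, cohort$fiducials, function(rec, fid) {
    extract_features(process_signal(rec, low = low, high = high, order = order),
                     fid, rmssd_method = rmssd_method)
  }) |> purrr::list_rbind()
  dplyr::bind_cols(
    tibble::tibble(subject_id = cohort$subject_id, stage = cohort$stage),
    feats
  )
}
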