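#' Construct a validated set of a/b-wave fiducials
#'
#' Holds the sample indices of the APG a waves (array `A`) and b waves
#' (array `B`) of one record. Indices are 0-based throughout the package, the
#' same convention used in annotation files. The constructor enforces the
#' strict interleaving `A[n] < B[n] < A[n+1]`: each beat's b wave follows its
#' a wave and precedes the next beat's a wave. `B` may hold one entry fewer
#' than `A` when the final beat's b wave is unavailable.
#'
#' @param a Integer vector of a-wave sample indices (0-based), sorted.
#' @param b Integer vector of b-wave sample indices (0-based), sorted;
#'   length `length(a)` or `length(a) - 1`.
#' @param n_samples Optional record length used to range-check indices.
#'
#' @return An object of class `fiducial_set`: list with `a`, `b` and
#'   `n_beats`.
#' @export
#' @examples
#' fid <- fiducial_set(a = c(10, 110), b = c(25, 126), n_samples = 200)
#' fid$n_beats
fiducial_set <- function(a, b, n_samples = NULL) {
  a <- as.integer(a)
  b <- as.integer(b)
  if (anyNA(a) || anyNA(b)) stop("fiducial indices must not be NA", call. = FALSE)
  n <- length(a)
  if (!(length(b) %in% c(n, max(n - 1L, 0L)))) {
    stop(sprintf("length(b) must be %d or %d, got %d", n, max(n - 1L, 0L), length(b)),
         call. = FALSE)
  }
  if (n > 1L && any(diff(a) <= 0L)) stop("a-wave indices must be strictly increasing", call. = FALSE)
  if (length(b) > 1L && any(diff(b) <= 0L)) stop("b-wave indices must be strictly increasing", call. = FALSE)
  if (any(a < 0L) || any(b < 0L)) stop("fiducial indices must be non-negative", call. = FALSE)
  if (!is.null(n_samples)) {
    bad <- c(a, b) >= n_samples
    if (any(bad)) {
      stop(sprintf("fiducial index %d outside the record (n_samples = %d)",
                   max(c(a, b)), as.integer(n_samples)), call. = FALSE)
    }
  }
  for (i in seq_along(b)) {
    if (b[i] <= a[i]) {
      stop(sprintf("beat %d: b wave (%d) does not follow its a wave (%d)", i, b[i], a[i]),
           call. = FALSE)
    }
    if (i < n && b[i] >= a[i + 1L]) {
      stop(sprintf("beat %d: b wave (%d) does not precede the next a wave (%d)",
                   i, b[i], a[i + 1L]), call. = FALSE)
    }
  }
  structure(list(a = a, b = b, n_beats = n), class = "fiducial_set")
}

#' @export
print.fiducial_set <- function(x, ...) {
  cat(sprintf("<fiducial_set> %d beats (%d b waves)\n", x$n_beats, length(x$b)))
  invisible(x)
}

#' Beat-to-beat (aa) intervals
#'
#' Distances between consecutive a waves, `aa[n] = A[n+1] - A[n]`, the
#' APG-derived surrogate of the RR interval series. Values are returned in
#' samples; divide by the sampling rate for seconds (as [rmssd()] does).
#'
#' @param fiducials A [fiducial_set()] with at least 2 beats.
#' @return Integer vector of length `n_beats - 1`, all positive.
#' @export
#' @examples
#' aa_intervals(fiducial_set(a = c(0, 367, 734), b = c(40, 407, 774)))
aa_intervals <- function(fiducials) {
  stopifnot(inherits(fiducials, "fiducial_set"))
  if (fiducials$n_beats < 2L) {
    stop("need at least 2 a waves to form an aa interval", call. = FALSE)
  }
  diff(fiducials$a)
}

#' Locate a and b waves from known beat onsets
#'
#' Derives ground-truth fiducials from an APG signal when the beat onsets
#' are known exactly -- as they are for synthetic records. Within each beat
#' the a wave is the APG maximum over the early part of the beat (the first
#' `search_frac` of the onset-to-onset span) and the b wave is the first
#' local minimum after the a wave whose value is negative (b waves lie below
#' the APG baseline by definition, so shallow positive ripples between a and
#' b are skipped). Beats without such a minimum before the next onset, or
#' whose indices would break the `A[n] < B[n] < A[n+1]` interleaving, are
#' dropped with a warning.
#'
#' @param apg Numeric APG vector.
#' @param beat_onsets Sorted 0-based sample indices of beat starts.
#' @param search_frac Fraction of each beat searched for the a wave.
#' @return A [fiducial_set()] (0-based indices).
#' @export
locate_ab_waves <- function(apg, beat_onsets, search_frac = 0.5) {
  stopifnot(is.numeric(apg), length(beat_onsets) >= 1L)
  beat_onsets <- as.integer(beat_onsets)
  if (is.unsorted(beat_onsets, strictly = TRUE)) {
    stop("`beat_onsets` must be strictly increasing", call. = FALSE)
  }
  n_total <- length(apg)
  ends <- c(beat_onsets[-1L], n_total)  # 0-based exclusive ends
  a_idx <- integer(0)
  b_idx <- integer(0)
  dropped <- 0L
  for (i in seq_along(beat_onsets)) {
    o <- beat_onsets[i]
    e <- ends[i]
    if (e - o < 5L) { dropped <- dropped + 1L; next }
    win <- (o + 1L):(o + max(1L, floor(search_frac * (e - o))))  # 1-based
    if (max(apg[win]) <= 0) { dropped <- dropped + 1L; next }    # flat / no a wave
    a1 <- win[which.max(apg[win])]                               # 1-based a
    if (a1 + 1L > e) { dropped <- dropped + 1L; next }
    seg <- apg[(a1 + 1L):e]
    b1 <- NA_integer_
    if (length(seg) >= 3L) {
      ds <- diff(seg)
      inner <- seg[2:(length(seg) - 1L)]
      turn <- which(ds[-length(ds)] < 0 & ds[-1L] >= 0 & inner < 0)
      if (length(turn)) b1 <- a1 + turn[1L] + 1L
    }
    if (is.na(b1)) { dropped <- dropped + 1L; next }
    # enforce interleaving with the previously accepted beat
    if (length(a_idx) && (a1 - 1L) <= b_idx[length(b_idx)]) { dropped <- dropped + 1L; next }
    a_idx <- c(a_idx, a1 - 1L)
    b_idx <- c(b_idx, b1 - 1L)
  }
  if (dropped > 0L) {
    warning(sprintf("locate_ab_waves: dropped %d of %d beats (no valid a/b pair)",
                    dropped, length(beat_onsets)), call. = FALSE)
  }
  fiducial_set(a_idx, b_idx, n_samples = n_total)
}
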