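#' Zero-phase Butterworth bandpass filter
#'
#' Filters a PPG signal with a Butterworth bandpass applied forward and
#' backward, so the output has exactly zero phase shift and waveform peaks
#' keep their sample positions. The default 0.5--7 Hz band removes baseline
#' wander and high-frequency noise while retaining the pulse harmonics that
#' shape the a and b waves of the second derivative.
#'
#' The forward-backward application squares the magnitude response, so a
#' second-order design yields a fourth-order effective magnitude. Startup
#' transients are suppressed by odd-reflection padding of the signal over
#' roughly three time constants of the slow (high-pass) band edge before
#' filtering; the padding is discarded afterwards.
#'
#' @param x Numeric vector of samples, or a [ppg_record()].
#' @param fs Sampling rate in Hz (ignored when `x` is a `ppg_record`).
#' @param low,high Band edges in Hz; must satisfy `0 < low < high < fs / 2`.
#' @param order Butterworth design order of one pass (default 2).
#'
#' @return Numeric vector of filtered samples, same length as the input,
#'   with DC removed.
#' @export
#' @examples
#' fs <- 367
#' x <- sin(2 * pi * 3 * seq(0, 5, by = 1 / fs)) + 10
#' y <- bandpass_filter(x, fs)
#' max(abs(y))          # close to 1: 3 Hz lies in the passband
#' abs(mean(y)) < 1e-6  # DC removed
bandpass_filter <- function(x, fs = NULL, low = 0.5, high = 7, order = 2) {
  if (inherits(x, "ppg_record")) {
    fs <- x$fs
    x <- x$samples
  }
  if (is.null(fs)) stop("`fs` is required when `x` is a plain vector", call. = FALSE)
  if (!is.numeric(low) || !is.numeric(high) || low <= 0 || high <= low || high >= fs / 2) {
    stop("invalid band: need 0 < low < high < fs/2", call. = FALSE)
  }
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  # padding must outlast the high-pass transient (~1/low seconds)
  padlen <- min(length(x) - 1L, ceiling(3 * fs / low))
  filtfilt_padded(bf$b, bf$a, x, padlen)
}

# Forward-backward IIR filtering with odd-reflection padding. Zero initial
# conditions are safe because the padding spans the filter transient.
filtfilt_padded <- function(b, a, x, padlen) {
  n <- length(x)
  if (n < 3L) stop("signal too short to filter", call. = FALSE)
  p <- max(1L, min(n - 1L, as.integer(padlen)))
  xp <- c(2 * x[1] - x[(p + 1):2], x, 2 * x[n] - x[(n - 1):(n - p)])
  y <- as.numeric(signal::filter(b, a, xp))
  y <- rev(as.numeric(signal::filter(b, a, rev(y))))
  y[(p + 1):(p + n)]
}

#' Three-point central first derivative
#'
#' Differentiates a sampled signal with the three-point central scheme
#' `y[n] = (x[n+1] - x[n-1]) / (2T)`, `T = 1/fs`. The scheme is exact for
#' linear signals and second-order accurate otherwise. The two boundary
#' samples use one-sided first differences and should be treated as
#' untrusted (see the `valid_range` of [process_signal()]).
#'
#' With `causal = TRUE` the same kernel is realized without look-ahead,
#' `y[n] = (x[n] - x[n-2]) / (2T)`, which reproduces the central estimate
#' delayed by one sample -- the streaming form whose cascade has a total
#' latency of two samples.
#'
#' @param x Numeric vector, length at least 3.
#' @param fs Sampling rate in Hz.
#' @param causal Use the delayed streaming form instead of the centred one.
#' @return Numeric vector of the same length as `x`.
#' @export
#' @examples
#' central_derivative(c(0, 1, 2, 3, 4), fs = 1)  # slope 1 everywhere
central_derivative <- function(x, fs, causal = FALSE) {
  n <- length(x)
  if (n < 3L) stop("need at least 3 samples to differentiate", call. = FALSE)
  d <- numeric(n)
  if (causal) {
    d[3:n] <- (x[3:n] - x[1:(n - 2)]) * fs / 2
    d[2] <- (x[2] - x[1]) * fs
    d[1] <- 0
  } else {
    d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) * fs / 2
    d[1] <- (x[2] - x[1]) * fs
    d[n] <- (x[n] - x[n - 1]) * fs
  }
  d
}

#' Second derivative (APG) by cascaded central differences
#'
#' Applies [central_derivative()] twice, producing the acceleration
#' plethysmogram (APG) from a filtered PPG. The cascaded scheme is exact in
#' the interior for polynomials up to degree 3, and maps a sinusoid
#' `sin(w n T)` to `-sin(w n T) * (sin(w T) / T)^2`.
#'
#' @inheritParams central_derivative
#' @return Numeric vector of the same length as `x`. The two samples at each
#'   end come from one-sided boundary rules and are untrusted.
#' @export
#' @examples
#' t <- (0:10) / 10
#' second_derivative(t^2, fs = 10)[3:9]  # exactly 2 in the interior
second_derivative <- function(x, fs, causal = FALSE) {
  if (length(x) < 5L) stop("need at least 5 samples for the second derivative", call. = FALSE)
  central_derivative(central_derivative(x, fs, causal = causal), fs, causal = causal)
}

#' Filter a record and derive its APG
#'
#' Runs the full preprocessing chain on one record: zero-phase Butterworth
#' bandpass, then the three-point first and second derivatives. The result
#' holds the filtered PPG, its first derivative and the APG, all aligned
#' sample-for-sample with the input.
#'
#' @param record A [ppg_record()].
#' @param low,high,order Filter design, see [bandpass_filter()].
#' @return An object of class `ppg_processed`: list with `ppg_filtered`,
#'   `deriv1`, `apg`, `fs`, and `valid_range` (the index interval that
#'   excludes the two derivative edge samples at each end).
#' @export
#' @examples
#' stages <- heat_stress_stages()
#' rec <- generate_record(stages$BE, seed = 1)
#' p <- process_signal(rec$record)
#' p$valid_range
process_signal <- function(record, low = 0.5, high = 7, order = 2) {
  stopifnot(inherits(record, "ppg_record"))
  s <- bandpass_filter(record, low = low, high = high, order = order)
  d1 <- central_derivative(s, record$fs)
  z <- central_derivative(d1, record$fs)
  structure(
    list(ppg_filtered = s, deriv1 = d1, apg = z, fs = record$fs,
         valid_range = c(3L, length(s) - 2L)),
    class = "ppg_processed"
  )
}

#' @export
print.ppg_processed <- function(x, ...) {
  cat(sprintf("<ppg_processed> %d samples @ %.6g Hz, valid range [%d, %d]\n",
              length(x$ppg_filtered), x$fs, x$valid_range[1], x$valid_range[2]))
  invisible(x)
}
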