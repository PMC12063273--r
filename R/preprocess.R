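#' Low-pass filter specification
#'
#' The default matches the signal conditioning used throughout the pipeline:
#' a second-order low-pass Butterworth at 15 Hz applied zero-phase
#' (forward and backward, giving an effective fourth-order magnitude response
#' and zero group delay). Both marker and force channels use the same spec.
#'
#' @param order filter design order (before the forward-backward pass).
#' @param cutoff_hz cutoff frequency in Hz.
#' @return an object of class `filter_spec`.
#' @export
filter_spec <- function(order = 2L, cutoff_hz = 15) {
  assert_scalar_positive(order, "order")
  assert_scalar_positive(cutoff_hz, "cutoff_hz")
  structure(list(order = as.integer(order), cutoff_hz = cutoff_hz,
                 kind = "lowpass_butterworth", zero_phase = TRUE),
            class = "filter_spec")
}

# One causal pass of the Butterworth filter with steady-state initial
# conditions (the filter starts as if the first sample had been held forever),
# so constant signals pass exactly.
butter_pass <- function(x, coefs) {
  as.numeric(signal::filter(coefs$b, coefs$a, x,
                            init.x = rep(x[1L], length(coefs$b) - 1L),
                            init.y = rep(x[1L], length(coefs$a) - 1L)))
}

#' Zero-phase Butterworth low-pass filter
#'
#' Applies the filter forward then backward. The signal is extended at both
#' ends by odd reflection before filtering and cropped afterwards, confining
#' start-up transients to the (discarded) extensions; together with
#' steady-state initialisation this passes constants exactly and leaves
#' in-band sinusoids with zero phase shift.
#'
#' @param x uniformly sampled numeric series.
#' @param fs sampling rate in Hz; must exceed twice the cutoff.
#' @param spec a [filter_spec()].
#' @return filtered series, same length as `x`.
#' @export
filter_zero_phase <- function(x, fs, spec = filter_spec()) {
  assert_scalar_positive(fs, "fs")
  if (fs <= 2 * spec$cutoff_hz)
    parameter_error("sampling rate must exceed twice the filter cutoff")
  n <- length(x)
  min_len <- 3L * (2L * spec$order + 1L)
  if (n < min_len)
    parameter_error(sprintf("signal too short to filter (need >= %d samples)", min_len))
  coefs <- signal::butter(spec$order, spec$cutoff_hz / (fs / 2), type = "low")
  npad <- min(n - 1L, as.integer(ceiling(3 * fs / spec$cutoff_hz)))
  pre <- 2 * x[1L] - x[(npad + 1L):2L]
  post <- 2 * x[n] - x[(n - 1L):(n - npad)]
  xp <- c(pre, x, post)
  y <- butter_pass(xp, coefs)
  y <- rev(butter_pass(rev(y), coefs))
  y[(npad + 1L):(npad + n)]
}

#' Downsample a uniformly sampled series
#'
#' Resamples by evaluating the series on the output time grid (plain
#' decimation when the rate ratio is an integer, linear interpolation
#' otherwise). Intended for use after low-pass filtering: the 15 Hz filter
#' already acts as the anti-alias stage for the 1000 to 100 Hz reduction, so
#' no further filtering is applied here.
#'
#' @param x input series sampled at `fs_in`.
#' @param fs_in,fs_out input and output rates in Hz; `fs_in >= fs_out`.
#' @return series of length `round(length(x) * fs_out / fs_in)`.
#' @export
resample_series <- function(x, fs_in, fs_out) {
  assert_scalar_positive(fs_in, "fs_in")
  assert_scalar_positive(fs_out, "fs_out")
  if (fs_in < fs_out)
    parameter_error("upsampling is not supported (fs_in < fs_out)")
  n <- length(x)
  if (fs_in == fs_out) return(x)
  n_out <- round(n * fs_out / fs_in)
  t_out <- (seq_len(n_out) - 1) / fs_out
  ratio <- fs_in / fs_out
  if (abs(ratio - round(ratio)) < 1e-9) {
    idx <- 1L + as.integer(round(t_out * fs_in))
    idx <- pmin(idx, n)
    return(x[idx])
  }
  t_in <- (seq_len(n) - 1) / fs_in
  approx(t_in, x, xout = pmin(t_out, t_in[n]))$y
}

#' Trim the start and stop phases of a condition
#'
#' Removes the first `head_s` and final `tail_s` seconds from the force and
#' marker streams so only steady-state gait is analysed (defaults: 10 s head,
#' 5 s tail).
#'
#' @param recording a [grf_recording()].
#' @param markers a [marker_set()] covering the same wall-clock window, or
#'   `NULL`.
#' @param head_s,tail_s seconds to drop at the start/end.
#' @return list with elements `recording` and `markers`, trimmed.
#' @export
trim_condition <- function(recording, markers = NULL, head_s = 10, tail_s = 5) {
  dur <- length(recording$ap$left) / recording$fs_force
  if (dur <= head_s + tail_s)
    parameter_error(sprintf(
      "condition of %.1f s is too short to trim %g + %g s", dur, head_s, tail_s))
  keep <- function(v, fs) {
    i0 <- as.integer(round(head_s * fs)) + 1L
    i1 <- length(v) - as.integer(round(tail_s * fs))
    v[i0:i1]
  }
  rec <- recording
  rec$ap <- lapply(rec$ap, keep, fs = rec$fs_force)
  if (!is.null(rec$vertical))
    rec$vertical <- lapply(rec$vertical, keep, fs = rec$fs_force)
  mk <- markers
  if (!is.null(mk)) {
    mk$ap <- lapply(mk$ap, keep, fs = mk$fs_marker)
    mk$ml <- lapply(mk$ml, keep, fs = mk$fs_marker)
  }
  list(recording = rec, markers = mk)
}
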