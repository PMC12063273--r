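# Shared fixtures, all built in code.

# Half-sine lobe of amplitude A (N) and duration T (s) at rate fs, embedded
# between zero-padding segments; returns the segment and the closed-form
# area 2*A*T/pi.
half_sine_segment <- function(A, T, fs, pad_s = 0.1) {
  npad <- round(pad_s * fs)
  t <- seq(0, T, by = 1 / fs)
  lobe <- A * sin(pi * t / T)
  list(x = c(rep(0, npad), lobe, rep(0, npad)),
       area = 2 * A * T / pi,
       peak_index = npad + which.max(lobe))
}

# A minimal stroke parameter set for fast cohort-level tests.
fast_params <- function() {
  p <- default_params()
  p$stroke$n_participants <- 4
  p$control$n_participants <- 4
  p
}

# Build a data.frame of fake step metrics for summarize/exclusion tests.
fake_steps <- function(n_left, n_right, peak = 1.5, impulse = 0.25,
                       n_invalid_left = 0) {
  df <- data.frame(
    leg = c(rep("left", n_left), rep("right", n_right)),
    peak = peak, impulse = impulse, valid = TRUE,
    stringsAsFactors = FALSE)
  if (n_invalid_left > 0) df$valid[seq_len(n_invalid_left)] <- FALSE
  df
}

# Match recovered steps to ground-truth rendered events by initial-contact
# time (the pipeline works on the trimmed clock, events on the condition
# clock).
match_steps_to_events <- function(step_df, events, leg, head_s = 10) {
  got <- step_df[step_df$leg == leg & step_df$valid, , drop = FALSE]
  ev <- events[events$leg == leg & !events$crossover, , drop = FALSE]
  got$ic_s <- head_s + (got$ic_index - 1) / 100
  idx <- vapply(got$ic_s, function(t) which.min(abs(ev$ic_s - t)), 1L)
  data.frame(got, truth_step = ev$step_index[idx],
             dt = abs(got$ic_s - ev$ic_s[idx]))
}
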