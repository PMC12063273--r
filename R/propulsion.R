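#' Locate the propulsion peak within one stance phase
#'
#' The propulsion peak is the maximum of the positive (propulsive, anterior)
#' portion of the stance-phase AP-GRF. Ties resolve to the latest index,
#' since propulsion occurs in late stance. A stance with no positive sample
#' has no propulsion and is reported invalid rather than raising an error.
#'
#' @param ap_grf AP-GRF samples over exactly one stance phase (N).
#' @return list with `peak_index`, `peak_value`, and `valid` (FALSE when the
#'   segment never becomes positive).
#' @export
find_propulsion_peak <- function(ap_grf) {
  if (!length(ap_grf) || all(ap_grf <= 0))
    return(list(peak_index = NA_integer_, peak_value = NA_real_, valid = FALSE))
  m <- max(ap_grf)
  idx <- max(which(ap_grf == m))
  list(peak_index = idx, peak_value = m, valid = TRUE)
}

#' Delimit the propulsion window around a peak
#'
#' The window is bounded by the zero-crossings enclosing the propulsive
#' region (zero-crossing = sign change between adjacent samples; the
#' crossing index is the first sample of the new sign; the window is
#' half-open `[start, end)`). An interior negative dip separating two
#' propulsive lobes is bridged — its area will subtract from the impulse —
#' while a trailing (or leading) negative lobe with no propulsive signal
#' beyond it is excluded. Two numerical guards make the rule robust on
#' filtered data: a positive excursion only counts as a propulsive lobe if
#' it exceeds 1% of the peak value (filter ripple never triggers bridging),
#' and a dip is only bridgeable while it stays shallower than half the peak
#' (the early-stance braking lobe is never absorbed into the window).
#'
#' @param ap_grf stance-phase AP-GRF samples (N).
#' @param peak_index index of the propulsion peak within `ap_grf`.
#' @return list with `start_index`, `end_index`, `peak_index`, `bridged_dips`
#'   (number of interior negative dips included in the window).
#' @export
delimit_propulsion_window <- function(ap_grf, peak_index) {
  n <- length(ap_grf)
  if (is.na(peak_index) || peak_index < 1L || peak_index > n)
    parameter_error("`peak_index` must index into `ap_grf`")
  if (ap_grf[peak_index] <= 0)
    parameter_error("`peak_index` must point at a positive sample")
  run <- rle(ap_grf > 0)
  run_end <- cumsum(run$lengths)
  run_start <- run_end - run$lengths + 1L
  peak_val <- ap_grf[peak_index]
  is_lobe <- vapply(seq_along(run$values), function(k) {
    run$values[k] && max(ap_grf[run_start[k]:run_end[k]]) >= 0.01 * peak_val
  }, TRUE)
  gap_bridgeable <- function(k) {  # non-positive run k shallow enough?
    min(ap_grf[run_start[k]:run_end[k]]) > -0.5 * peak_val
  }
  peak_run <- which(run_start <= peak_index & run_end >= peak_index)
  # grow the window lobe by lobe while the next real lobe is reachable
  # across bridgeable gaps only
  lo <- peak_run
  repeat {
    nxt <- which(is_lobe & seq_along(run$values) < lo)
    if (!length(nxt)) break
    nxt <- max(nxt)
    gaps <- setdiff(seq(nxt + 1L, lo - 1L), integer(0))
    if (length(gaps) && !all(vapply(gaps, gap_bridgeable, TRUE))) break
    lo <- nxt
  }
  hi <- peak_run
  repeat {
    nxt <- which(is_lobe & seq_along(run$values) > hi)
    if (!length(nxt)) break
    nxt <- min(nxt)
    gaps <- setdiff(seq(hi + 1L, nxt - 1L), integer(0))
    if (length(gaps) && !all(vapply(gaps, gap_bridgeable, TRUE))) break
    hi <- nxt
  }
  start <- run_start[lo]
  end <- run_end[hi]
  bridged <- sum(rle(ap_grf[start:end] < 0)$values)
  list(start_index = start, end_index = end + 1L, peak_index = peak_index,
       bridged_dips = as.integer(bridged))
}

#' Signed impulse over a propulsion window
#'
#' Trapezoidal time-integral of the AP-GRF over the window, extended by one
#' sample on each side (when available) so the near-zero boundary samples at
#' the crossings contribute their slivers; interior bridged dips subtract.
#'
#' @param ap_grf stance-phase AP-GRF samples (N).
#' @param window list from [delimit_propulsion_window()].
#' @param fs sampling rate in Hz.
#' @return impulse in N.s.
#' @export
compute_impulse <- function(ap_grf, window, fs) {
  i0 <- max(1L, window$start_index - 1L)
  i1 <- min(length(ap_grf), window$end_index)
  trapz_series(ap_grf[i0:i1], fs)
}

#' Normalize a force quantity by body mass
#'
#' @param value force (N) or impulse (N.s).
#' @param body_mass_kg body mass in kg.
#' @return value in N/kg or N/kg.s.
#' @export
normalize_by_mass <- function(value, body_mass_kg) {
  assert_scalar_positive(body_mass_kg, "body_mass_kg")
  value / body_mass_kg
}

#' Per-step propulsion metrics for a set of stance phases
#'
#' Runs peak detection, window delimitation, impulse integration and mass
#' normalization for every stance phase. Phases already invalid (crossover,
#' edge) are carried through unscored; stances without a positive lobe are
#' marked invalid with reason `"no_propulsion"`.
#'
#' @param ap_by_leg named list (`left`, `right`) of AP-GRF series at `fs`
#'   (N), one channel per plate.
#' @param phases stance phases from [flag_crossover_steps()].
#' @param fs sampling rate of `ap_by_leg` in Hz.
#' @param body_mass_kg participant mass.
#' @return data.frame with `leg`, `step_index`, `ic_index`, `tc_index`,
#'   `peak` (N/kg), `impulse` (N/kg.s), `bridged_dips`, `valid`, `reason`.
#' @export
extract_step_metrics <- function(ap_by_leg, phases, fs, body_mass_kg) {
  out <- phases
  out$step_index <- stats::ave(seq_len(nrow(out)), out$leg, FUN = seq_along)
  out$peak <- NA_real_
  out$impulse <- NA_real_
  out$bridged_dips <- NA_integer_
  out$reason <- out$exclusion_reason
  for (i in seq_len(nrow(out))) {
    if (!out$valid[i]) next
    seg <- ap_by_leg[[out$leg[i]]][out$ic_index[i]:(out$tc_index[i] - 1L)]
    pk <- find_propulsion_peak(seg)
    if (!pk$valid) {
      out$valid[i] <- FALSE
      out$reason[i] <- "no_propulsion"
      next
    }
    win <- delimit_propulsion_window(seg, pk$peak_index)
    out$peak[i] <- normalize_by_mass(pk$peak_value, body_mass_kg)
    out$impulse[i] <- normalize_by_mass(compute_impulse(seg, win, fs), body_mass_kg)
    out$bridged_dips[i] <- win$bridged_dips
  }
  out$exclusion_reason <- NULL
  out
}

#' Summarize per-step metrics for one condition
#'
#' Arithmetic means of peak and impulse over valid steps, per leg. A
#' condition is included only if every expected leg reaches the minimum step
#' count (default 23 valid steps per leg).
#'
#' @param steps data.frame of per-step metrics with columns `leg`, `peak`,
#'   `impulse`, `valid`.
#' @param speed condition belt speed (m/s), carried through.
#' @param condition_id condition identifier, carried through.
#' @param is_cws whether this is the comfortable-walking-speed condition.
#' @param min_steps minimum valid steps per leg for inclusion.
#' @param legs legs the condition must provide (default both).
#' @return one-row-per-leg data.frame plus attributes `included` and
#'   `exclusion_reason` (`"none"` or `"too_few_steps"`).
#' @export
summarize_condition <- function(steps, speed, condition_id, is_cws = FALSE,
                                min_steps = 23L, legs = c("left", "right")) {
  per_leg <- lapply(legs, function(lg) {
    sub <- steps[steps$leg == lg & steps$valid, , drop = FALSE]
    data.frame(condition_id = condition_id, speed = speed, is_cws = is_cws,
               leg = lg, n_steps = nrow(sub),
               peak = if (nrow(sub)) mean(sub$peak) else NA_real_,
               impulse = if (nrow(sub)) mean(sub$impulse) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, per_leg)
  too_few <- any(out$n_steps < min_steps)
  attr(out, "included") <- !too_few
  attr(out, "exclusion_reason") <- if (too_few) "too_few_steps" else "none"
  out
}

#' Participant-level exclusion rule
#'
#' A participant is excluded when two or more conditions fail the minimum
#' step count; with a single failing condition only that condition is
#' dropped.
#'
#' @param condition_list list of per-condition summaries from
#'   [summarize_condition()].
#' @param max_failed maximum number of failing conditions a retained
#'   participant may have (default 1).
#' @return list with `include_participant`, `kept` (row-bound included
#'   conditions), and `report` (one row per condition with its fate).
#' @export
apply_participant_exclusion <- function(condition_list, max_failed = 1L) {
  reasons <- vapply(condition_list, function(x) attr(x, "exclusion_reason"), "")
  failed <- reasons == "too_few_steps"
  include <- sum(failed) <= max_failed
  report <- data.frame(
    condition_id = vapply(condition_list, function(x) x$condition_id[1L], ""),
    speed = vapply(condition_list, function(x) x$speed[1L], 0),
    exclusion_reason = reasons,
    kept = include & !failed,
    stringsAsFactors = FALSE)
  kept <- if (include) do.call(rbind, condition_list[!failed]) else NULL
  list(include_participant = include, kept = kept, report = report)
}
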