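# Local extrema with a minimum separation: candidate maxima are strict rises
# followed by non-rises; ties within the separation window resolve to the
# higher peak. Candidates must reach the upper part of the signal's range
# (prominence guard: numerical ripple in flat stretches of an otherwise
# moving trajectory is never an event). Returns an increasing index vector
# (possibly empty).
find_local_maxima <- function(x, min_sep, prominence_frac = 0.6) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  cand <- which(x[2:(n - 1L)] > x[1:(n - 2L)] & x[2:(n - 1L)] >= x[3:n]) + 1L
  if (!length(cand)) return(integer(0))
  rng <- max(x) - min(x)
  cand <- cand[x[cand] >= min(x) + prominence_frac * rng]
  if (!length(cand)) return(integer(0))
  ord <- cand[order(x[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (i in ord) {
    if (!length(kept) || all(abs(kept - i) >= min_sep)) kept <- c(kept, i)
  }
  sort(kept)
}

# Nominal cadence model: steps/min (both feet) as a linear function of belt
# speed. Used for the event detector's minimum peak separation and by the
# synthetic generator's step counts.
cadence_steps_per_min <- function(speed, intercept = 60, slope = 40) {
  intercept + slope * speed
}

#' Estimate stance phases from foot-marker trajectories
#'
#' Kinematic event detection for treadmill gait: initial contact (IC) is the
#' forward extremum of the heel marker's AP position relative to the pelvis
#' reference; terminal contact (TC) is the backward extremum of the toe
#' marker's AP position relative to the pelvis. Events of each leg must
#' alternate IC, TC, IC, ...; the trailing partial cycle is dropped. Stance
#' intervals are half-open `[ic, tc)` in 1-based sample indices at the marker
#' rate.
#'
#' @param markers a filtered [marker_set()].
#' @param belt_speed belt speed in m/s (sets the expected stride time for the
#'   detector's minimum peak separation).
#' @param min_sep_factor minimum peak separation as a fraction of the
#'   expected stride time.
#' @param cadence_model `c(intercept, slope)` of the nominal cadence model in
#'   steps/min per m/s.
#' @return data.frame with columns `leg`, `ic_index`, `tc_index`, `valid`,
#'   `exclusion_reason` ("none", "edge", or "duration"). A leg with no
#'   detectable motion yields zero rows; if neither leg yields events a
#'   detection error is raised.
#' @export
detect_stance_phases <- function(markers, belt_speed, min_sep_factor = 0.4,
                                 cadence_model = c(60, 40)) {
  assert_scalar_positive(belt_speed, "belt_speed")
  fs <- markers$fs_marker
  stride_s <- 120 / cadence_steps_per_min(belt_speed, cadence_model[1], cadence_model[2])
  min_sep <- max(2L, as.integer(round(min_sep_factor * stride_s * fs)))
  pelvis <- markers$ap$pelvis
  n <- length(pelvis)

  one_leg <- function(leg) {
    heel <- markers$ap[[paste0("heel_", leg)]] - pelvis
    toe <- markers$ap[[paste0("toe_", leg)]] - pelvis
    ics <- find_local_maxima(heel, min_sep)
    tcs <- find_local_maxima(-toe, min_sep)
    if (!length(ics) || !length(tcs)) return(NULL)
    rows <- list()
    for (k in seq_len(length(ics) - 1L)) {
      between <- tcs[tcs > ics[k] & tcs < ics[k + 1L]]
      if (length(between) != 1L)
        detection_error(sprintf(
          "non-alternating gait events on %s leg: %d terminal contacts between initial contacts at samples %d and %d (ICs: %s; TCs: %s)",
          leg, length(between), ics[k], ics[k + 1L],
          paste(ics, collapse = ","), paste(tcs, collapse = ",")))
      rows[[k]] <- c(ic = ics[k], tc = between)
    }
    if (!length(rows)) return(NULL)
    m <- do.call(rbind, rows)
    dur_s <- (m[, "tc"] - m[, "ic"]) / fs
    edge <- m[, "ic"] <= 1L | m[, "tc"] >= n
    bad_dur <- dur_s < 0.2 | dur_s > 2.5
    data.frame(leg = leg, ic_index = as.integer(m[, "ic"]),
               tc_index = as.integer(m[, "tc"]),
               valid = !(edge | bad_dur),
               exclusion_reason = ifelse(edge, "edge",
                                         ifelse(bad_dur, "duration", "none")),
               stringsAsFactors = FALSE)
  }

  res <- lapply(c("left", "right"), one_leg)
  if (all(vapply(res, is.null, TRUE)))
    detection_error("no gait events detectable on either leg (flat marker trajectories?)")
  out <- do.call(rbind, res[!vapply(res, is.null, TRUE)])
  rownames(out) <- NULL
  out
}

#' Flag crossover steps from mediolateral foot placement
#'
#' A stance phase is a crossover (and invalid for per-plate force
#' attribution) if at any sample during the phase the contralateral foot's
#' heel or toe ML coordinate lies on, or across, the belt midline towards the
#' stance side. The package ML convention places the left belt at negative
#' ML, so the boundary (exactly on the midline) counts as partially placed.
#'
#' @param phases data.frame from [detect_stance_phases()].
#' @param markers the [marker_set()] the phases were detected on.
#' @param belt_midline ML coordinate of the belt gap (default 0).
#' @return `phases` with `valid`/`exclusion_reason` updated for crossovers.
#' @export
flag_crossover_steps <- function(phases, markers, belt_midline = 0) {
  if (!nrow(phases)) return(phases)
  for (i in seq_len(nrow(phases))) {
    if (!phases$valid[i]) next
    idx <- phases$ic_index[i]:(phases$tc_index[i] - 1L)
    contra <- if (phases$leg[i] == "left") "right" else "left"
    heel_ml <- markers$ml[[paste0("heel_", contra)]][idx]
    toe_ml <- markers$ml[[paste0("toe_", contra)]][idx]
    crossed <- if (phases$leg[i] == "left") {
      any(heel_ml <= belt_midline) || any(toe_ml <= belt_midline)
    } else {
      any(heel_ml >= belt_midline) || any(toe_ml >= belt_midline)
    }
    if (crossed) {
      phases$valid[i] <- FALSE
      phases$exclusion_reason[i] <- "crossover"
    }
  }
  phases
}

#' Count valid steps per leg
#'
#' @param phases data.frame of stance phases with a `valid` column.
#' @return named integer vector, one count per leg present in `phases`.
#' @export
count_valid_steps <- function(phases) {
  if (!nrow(phases)) return(integer(0))
  tapply(phases$valid, phases$leg, sum)
}
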