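#' Ground-reaction-force recording for one treadmill condition
#'
#' Container for the per-plate anteroposterior ground reaction force (AP-GRF)
#' of a split-belt instrumented treadmill. Anterior (propulsive) force is
#' positive; each belt has its own force plate, so the left channel carries
#' the left leg's stance forces (crossover steps excepted, which are flagged
#' downstream and never scored).
#'
#' @param ap_left,ap_right AP-GRF in newtons for the left/right plate.
#' @param fs_force sampling rate in Hz (native acquisition 1000 Hz).
#' @param body_mass_kg participant body mass in kg, used for normalization.
#' @param condition_id identifier linking the recording to its schedule entry.
#' @param vertical_left,vertical_right optional vertical force channels (N).
#' @return an object of class `grf_recording`.
#' @export
grf_recording <- function(ap_left, ap_right, fs_force, body_mass_kg,
                          condition_id = NA_character_,
                          vertical_left = NULL, vertical_right = NULL) {
  if (length(ap_left) != length(ap_right))
    format_error("left and right AP-GRF channels must have equal length")
  assert_scalar_positive(fs_force, "fs_force")
  assert_scalar_positive(body_mass_kg, "body_mass_kg")
  structure(
    list(ap = list(left = as.numeric(ap_left), right = as.numeric(ap_right)),
         vertical = if (is.null(vertical_left)) NULL else
           list(left = as.numeric(vertical_left),
                right = as.numeric(vertical_right)),
         fs_force = fs_force,
         body_mass_kg = body_mass_kg,
         condition_id = condition_id),
    class = "grf_recording")
}

#' @export
print.grf_recording <- function(x, ...) {
  cat(sprintf("<grf_recording> %d samples @ %g Hz (%.1f s), mass %.1f kg, condition %s\n",
              length(x$ap$left), x$fs_force,
              length(x$ap$left) / x$fs_force, x$body_mass_kg,
              as.character(x$condition_id)))
  invisible(x)
}

#' Required marker labels for gait-event estimation
#'
#' Only the foot and pelvis markers of the full marker protocol are used:
#' left/right calcaneus (heel), left/right second metatarsal head (toe), and
#' a pelvis reference (mean of the iliac-spine markers).
#' @export
marker_labels <- function() {
  c("heel_left", "toe_left", "heel_right", "toe_right", "pelvis")
}

#' Marker trajectory set
#'
#' Anteroposterior (AP, along belt travel) and mediolateral (ML) coordinates
#' in metres for the foot and pelvis markers, sampled at `fs_marker`
#' (native 100 Hz). The ML coordinates are only used for crossover-step
#' flagging; by package convention the left belt lies at negative ML.
#'
#' @param ap named list of numeric vectors (m), names per [marker_labels()].
#' @param ml named list of numeric vectors (m), same names and lengths.
#' @param fs_marker sampling rate in Hz.
#' @return an object of class `marker_set`.
#' @export
marker_set <- function(ap, ml, fs_marker) {
  req <- marker_labels()
  missing_ap <- setdiff(req, names(ap))
  missing_ml <- setdiff(req, names(ml))
  if (length(missing_ap) || length(missing_ml))
    format_error(paste0("missing marker trajectories: ",
                        paste(unique(c(missing_ap, missing_ml)), collapse = ", ")))
  lens <- c(vapply(ap[req], length, 1L), vapply(ml[req], length, 1L))
  if (length(unique(lens)) != 1L)
    format_error("all marker trajectories must share the same length")
  assert_scalar_positive(fs_marker, "fs_marker")
  structure(list(ap = lapply(ap[req], as.numeric),
                 ml = lapply(ml[req], as.numeric),
                 fs_marker = fs_marker),
            class = "marker_set")
}

#' @export
print.marker_set <- function(x, ...) {
  cat(sprintf("<marker_set> %d samples @ %g Hz, markers: %s\n",
              length(x$ap$pelvis), x$fs_marker,
              paste(names(x$ap), collapse = ", ")))
  invisible(x)
}

#' Condition schedule and participant metadata
#'
#' One row per treadmill condition. Durations follow the acquisition rule:
#' conditions above 0.4 m/s last 2 min, conditions at or below 0.4 m/s last
#' 3 min (slower belts need longer to accumulate enough strides).
#'
#' @param speeds belt speeds in m/s.
#' @param is_cws logical flags marking the comfortable-walking-speed condition.
#' @param group `"stroke"` or `"control"`.
#' @param paretic_side `"left"`, `"right"`, or `"none"` for controls.
#' @param cws comfortable walking speed in m/s.
#' @param condition_id optional identifiers; defaults to `C1..Cn`.
#' @param durations_s optional durations; defaults to the 2/3-minute rule.
#' @return a data.frame of class `condition_schedule` with attributes
#'   `group`, `paretic_side`, `cws`.
#' @export
condition_schedule <- function(speeds, is_cws, group, paretic_side, cws,
                               condition_id = NULL, durations_s = NULL) {
  if (any(speeds <= 0)) parameter_error("belt speeds must be positive")
  if (length(is_cws) != length(speeds))
    parameter_error("`is_cws` must match `speeds` in length")
  if (is.null(durations_s)) durations_s <- condition_duration(speeds)
  if (is.null(condition_id)) condition_id <- sprintf("C%d", seq_along(speeds))
  out <- data.frame(condition_id = condition_id, speed = speeds,
                    duration_s = durations_s, is_cws = is_cws,
                    stringsAsFactors = FALSE)
  structure(out, class = c("condition_schedule", "data.frame"),
            group = match.arg(group, c("stroke", "control")),
            paretic_side = match.arg(paretic_side, c("left", "right", "none")),
            cws = cws)
}

#' Condition duration rule
#'
#' @param speed belt speed(s) in m/s.
#' @return duration in seconds: 180 for speeds at or below 0.4 m/s, 120 above.
#' @export
condition_duration <- function(speed) {
  ifelse(speed <= 0.4, 180, 120)
}
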