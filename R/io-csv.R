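#' CSV dialect description for treadmill exports
#'
#' Treadmill CSV exports vary too much to sniff reliably, so the column
#' mapping is always explicit configuration. AP force is stored
#' anterior-positive internally; set `sign = -1` for posterior-positive
#' sources. The AP axis is the belt travel axis by convention; which lab
#' axis that is must be encoded in the mapping, never auto-detected.
#'
#' @param ap_left,ap_right column names of the per-plate AP force channels.
#' @param time optional time column name (seconds); used to infer and check
#'   the sampling rate.
#' @param fs_force sampling rate in Hz (required when no time column).
#' @param force_unit `"N"` or `"kN"`.
#' @param sign `+1` if the source is anterior-positive, `-1` otherwise.
#' @param vertical_left,vertical_right optional vertical-force columns.
#' @param marker_path optional path to a companion marker CSV (markers are
#'   usually exported at their own rate, hence a separate file).
#' @param markers named list mapping each of [marker_labels()] to
#'   `c(ap = <col>, ml = <col>)` in the marker CSV.
#' @param fs_marker marker sampling rate in Hz.
#' @param marker_unit `"m"` or `"mm"`.
#' @return a `csv_dialect` list.
#' @export
csv_dialect <- function(ap_left, ap_right, time = NULL, fs_force = NULL,
                        force_unit = c("N", "kN"), sign = 1,
                        vertical_left = NULL, vertical_right = NULL,
                        marker_path = NULL, markers = NULL, fs_marker = NULL,
                        marker_unit = c("m", "mm")) {
  structure(list(ap_left = ap_left, ap_right = ap_right, time = time,
                 fs_force = fs_force, force_unit = match.arg(force_unit),
                 sign = sign, vertical_left = vertical_left,
                 vertical_right = vertical_right, marker_path = marker_path,
                 markers = markers, fs_marker = fs_marker,
                 marker_unit = match.arg(marker_unit)),
            class = "csv_dialect")
}

need_column <- function(df, col, what) {
  if (is.null(col)) return(NULL)
  if (!col %in% names(df))
    format_error(sprintf("column '%s' (mapped as %s) not found in file", col, what))
  df[[col]]
}

infer_fs <- function(time_values) {
  dt <- diff(time_values)
  if (any(dt <= 0))
    format_error("time column is not strictly increasing")
  if (max(dt) - min(dt) > 1e-6 * stats::median(dt) * 100)
    format_error("time column is not uniformly sampled")
  1 / stats::median(dt)
}

#' Read a force/marker recording from CSV
#'
#' @param path force CSV path.
#' @param dialect a [csv_dialect()]; markers are read from
#'   `dialect$marker_path` when mapped.
#' @param body_mass_kg participant mass (not stored in treadmill exports).
#' @param condition_id identifier for the recording.
#' @return list with `recording` ([grf_recording()]) and `markers`
#'   ([marker_set()] or `NULL`).
#' @export
read_recording_csv <- function(path, dialect, body_mass_kg,
                               condition_id = NA_character_) {
  if (!file.exists(path)) format_error(sprintf("file not found: %s", path))
  df <- read.csv(path, check.names = FALSE)
  unit <- if (dialect$force_unit == "kN") 1000 else 1
  ap_l <- need_column(df, dialect$ap_left, "ap_left") * unit * dialect$sign
  ap_r <- need_column(df, dialect$ap_right, "ap_right") * unit * dialect$sign
  fs <- dialect$fs_force
  if (!is.null(dialect$time)) {
    tv <- need_column(df, dialect$time, "time")
    fs_inferred <- infer_fs(tv)
    if (is.null(fs)) fs <- fs_inferred
  }
  if (is.null(fs)) format_error("no sampling rate: provide fs_force or a time column")
  v_l <- need_column(df, dialect$vertical_left, "vertical_left")
  v_r <- need_column(df, dialect$vertical_right, "vertical_right")
  rec <- grf_recording(ap_l, ap_r, fs_force = fs, body_mass_kg = body_mass_kg,
                       condition_id = condition_id,
                       vertical_left = if (is.null(v_l)) NULL else v_l * unit,
                       vertical_right = if (is.null(v_r)) NULL else v_r * unit)
  mk <- NULL
  if (!is.null(dialect$marker_path)) {
    mdf <- read.csv(dialect$marker_path, check.names = FALSE)
    mu <- if (dialect$marker_unit == "mm") 1e-3 else 1
    ap <- list(); ml <- list()
    for (lbl in marker_labels()) {
      map <- dialect$markers[[lbl]]
      if (is.null(map))
        format_error(sprintf("no column mapping for marker '%s'", lbl))
      ap[[lbl]] <- need_column(mdf, map[["ap"]], paste0(lbl, " AP")) * mu
      ml[[lbl]] <- need_column(mdf, map[["ml"]], paste0(lbl, " ML")) * mu
    }
    if (is.null(dialect$fs_marker))
      format_error("fs_marker required when markers are mapped")
    mk <- marker_set(ap, ml, fs_marker = dialect$fs_marker)
  }
  list(recording = rec, markers = mk)
}

observation_table_columns <- c(
  "participant_id", "group", "condition_id", "speed", "is_cws", "leg",
  "n_steps", "peak", "impulse", "peak_symmetry", "impulse_symmetry",
  "peak_symmetry_at_cws", "impulse_symmetry_at_cws")

#' Write the long-format observation table
#'
#' One row per participant, condition and leg, fixed column order, full
#' numeric precision (lossless round trip with
#' [read_observation_table()]).
#'
#' @param rows observation data.frame from [build_observation_table()].
#' @param path output CSV path.
#' @return (invisibly) the path.
#' @export
write_observation_table <- function(rows, path) {
  if (is.null(rows) || !nrow(rows))
    parameter_error("refusing to write an empty observation table")
  missing <- setdiff(observation_table_columns, names(rows))
  if (length(missing))
    format_error(paste0("observation rows lack columns: ",
                        paste(missing, collapse = ", ")))
  write.csv(rows[, observation_table_columns], path, row.names = FALSE)
  invisible(path)
}

#' Read an observation table written by [write_observation_table()]
#'
#' @param path CSV path.
#' @return observation data.frame.
#' @export
read_observation_table <- function(path) {
  if (!file.exists(path)) format_error(sprintf("file not found: %s", path))
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!identical(names(df), observation_table_columns))
    format_error("file does not match the observation-table schema")
  df$is_cws <- as.logical(df$is_cws)
  df
}
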