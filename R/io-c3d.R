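# Minimal C3D support (Intel byte order, floating-point data): a writer for
# synthetic recordings and a reader for the subset of the format the writer
# produces (plus well-behaved files with the same marker/analog labelling).
# This is not a general C3D parser; it covers the interchange needs of this
# pipeline only and is documented as such.

c3d_marker_label <- c(heel_left = "HEEL_L", toe_left = "TOE_L",
                      heel_right = "HEEL_R", toe_right = "TOE_R",
                      pelvis = "PELVIS")

pad_label <- function(x, width) {
  substr(paste0(x, strrep(" ", width)), 1, width)
}

# --- parameter-section serialization helpers -------------------------------

c3d_group_record <- function(id, name, last = FALSE) {
  nm <- charToRaw(name)
  offset <- if (last) 0L else 3L  # offset field (2) + desc-length byte (1)
  c(writeBin(as.integer(c(length(nm), -id)), raw(), size = 1),
    nm,
    writeBin(as.integer(offset), raw(), size = 2, endian = "little"),
    as.raw(0))
}

c3d_param_record <- function(gid, name, type, dims, data_raw, last = FALSE) {
  nm <- charToRaw(name)
  body <- c(writeBin(as.integer(type), raw(), size = 1),
            writeBin(length(dims), raw(), size = 1),
            if (length(dims)) writeBin(as.integer(dims), raw(), size = 1),
            data_raw,
            as.raw(0))
  offset <- if (last) 0L else 2L + length(body)
  c(writeBin(as.integer(c(length(nm), gid)), raw(), size = 1),
    nm,
    writeBin(as.integer(offset), raw(), size = 2, endian = "little"),
    body)
}

raw_float <- function(x) writeBin(as.numeric(x), raw(), size = 4, endian = "little")
raw_int16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")

c3d_char_param <- function(gid, name, labels, width) {
  data <- charToRaw(paste(vapply(labels, pad_label, "", width = width),
                          collapse = ""))
  c3d_param_record(gid, name, type = -1, dims = c(width, length(labels)), data)
}

#' Write a recording and marker set to a C3D file
#'
#' Points carry the marker trajectories (lab X = mediolateral, Y =
#' anteroposterior, Z = 0, metres); analog channels carry the per-plate AP
#' force (`FY1`/`FY2`, anterior-positive, N) and optionally vertical force
#' (`FZ1`/`FZ2`). The analog rate must be an integer multiple of the point
#' rate. Intel processor type, floating-point data.
#'
#' @param recording a [grf_recording()].
#' @param markers a [marker_set()].
#' @param path output path.
#' @param plates which plates' channels to write (test hook for the
#'   two-platform requirement of the reader).
#' @return (invisibly) the path.
#' @export
write_recording_c3d <- function(recording, markers, path,
                                plates = c("left", "right")) {
  fs_m <- markers$fs_marker
  fs_f <- recording$fs_force
  ratio <- fs_f / fs_m
  if (abs(ratio - round(ratio)) > 1e-9)
    parameter_error("analog rate must be an integer multiple of the point rate")
  ratio <- as.integer(round(ratio))
  n_frames <- length(markers$ap$pelvis)
  analog <- list()
  for (side in plates) {
    analog[[paste0("FY", match(side, c("left", "right")))]] <- recording$ap[[side]]
    if (!is.null(recording$vertical))
      analog[[paste0("FZ", match(side, c("left", "right")))]] <-
        recording$vertical[[side]]
  }
  analog <- lapply(analog, function(x) {
    length(x) <- n_frames * ratio
    x[is.na(x)] <- 0
    x
  })
  n_analog <- length(analog)
  labels <- unname(c3d_marker_label)
  n_pts <- length(labels)

  # parameter section
  recs <- c(
    c3d_group_record(1, "POINT"),
    c3d_param_record(1, "USED", 2, integer(0), raw_int16(n_pts)),
    c3d_param_record(1, "RATE", 4, integer(0), raw_float(fs_m)),
    c3d_param_record(1, "SCALE", 4, integer(0), raw_float(-1)),
    c3d_param_record(1, "FRAMES", 2, integer(0), raw_int16(n_frames)),
    c3d_char_param(1, "LABELS", labels, 8),
    c3d_group_record(2, "ANALOG"),
    c3d_param_record(2, "USED", 2, integer(0), raw_int16(n_analog)),
    c3d_param_record(2, "RATE", 4, integer(0), raw_float(fs_f)),
    c3d_char_param(2, "LABELS", names(analog), 8),
    c3d_param_record(2, "MASS", 4, integer(0),
                     raw_float(recording$body_mass_kg), last = TRUE))
  n_param_blocks <- as.integer(ceiling((length(recs) + 4) / 512))
  param <- c(writeBin(c(1L, 80L), raw(), size = 1),
             writeBin(n_param_blocks, raw(), size = 1),
             writeBin(84L, raw(), size = 1),
             recs)
  length(param) <- n_param_blocks * 512
  param[is.na(param)] <- as.raw(0)

  data_start <- 2L + n_param_blocks

  header <- c(
    writeBin(c(2L, 80L), raw(), size = 1),            # param block, magic
    raw_int16(n_pts),                                  # points used
    raw_int16(n_analog * ratio),                       # analog per frame
    raw_int16(1), raw_int16(n_frames),                 # first/last frame
    raw_int16(0),                                      # max gap
    raw_float(-1),                                     # scale: float data
    raw_int16(data_start),                             # data start block
    raw_int16(ratio),                                  # analog samples/frame
    raw_float(fs_m))                                   # point rate
  length(header) <- 512
  header[is.na(header)] <- as.raw(0)

  # data section: per frame, points (x, y, z, residual) then analog subframes
  frame_chunks <- vector("list", n_frames)
  lbls <- names(c3d_marker_label)
  ml_mat <- do.call(cbind, markers$ml[lbls])
  ap_mat <- do.call(cbind, markers$ap[lbls])
  an_mat <- do.call(cbind, analog)
  for (f in seq_len(n_frames)) {
    pts <- rbind(ml_mat[f, ], ap_mat[f, ], 0, 0)
    sub <- t(an_mat[((f - 1L) * ratio + 1L):(f * ratio), , drop = FALSE])
    frame_chunks[[f]] <- c(as.numeric(pts), as.numeric(sub))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(header, param), con)
  writeBin(unlist(frame_chunks), con, size = 4, endian = "little")
  invisible(path)
}

read_c3d_params <- function(raw_data, param_start) {
  pos <- param_start + 4L  # skip the 4 section-header bytes
  params <- list()
  repeat {
    if (pos > length(raw_data)) break
    nlen <- readBin(raw_data[pos], "integer", size = 1)
    if (nlen == 0) break
    gid <- readBin(raw_data[pos + 1L], "integer", size = 1)
    name <- rawToChar(raw_data[(pos + 2L):(pos + 1L + abs(nlen))])
    off_pos <- pos + 2L + abs(nlen)
    offset <- readBin(raw_data[off_pos:(off_pos + 1L)], "integer",
                      size = 2, endian = "little")
    if (gid > 0) {
      p <- off_pos + 2L
      type <- readBin(raw_data[p], "integer", size = 1)
      nd <- readBin(raw_data[p + 1L], "integer", size = 1)
      dims <- if (nd > 0)
        as.integer(raw_data[(p + 2L):(p + 1L + nd)]) else integer(0)
      dstart <- p + 2L + nd
      count <- max(1L, prod(dims))
      width <- if (type == -1) 1L else abs(type)
      nbytes <- count * width
      bytes <- raw_data[dstart:(dstart + nbytes - 1L)]
      value <- switch(as.character(type),
        "-1" = rawToChar(bytes),
        "1" = readBin(bytes, "integer", size = 1, n = count),
        "2" = readBin(bytes, "integer", size = 2, n = count, endian = "little"),
        "4" = readBin(bytes, "numeric", size = 4, n = count, endian = "little"))
      if (type == -1 && length(dims) == 2)
        value <- vapply(seq_len(dims[2]), function(i)
          trimws(substr(value, (i - 1) * dims[1] + 1, i * dims[1])), "")
      params[[paste0(gid, ":", name)]] <- value
    }
    if (offset == 0) break
    pos <- off_pos + offset
  }
  params
}

#' Read a recording and marker set from a C3D file
#'
#' Reads the subset of C3D written by [write_recording_c3d()]:
#' floating-point Intel files whose point labels include the five
#' [marker_labels()] markers (as `HEEL_L`, `TOE_L`, `HEEL_R`, `TOE_R`,
#' `PELVIS`) and whose analog labels include `FY1`/`FY2` (per-plate AP
#' force). Files with fewer than two force platforms are rejected.
#'
#' @param path C3D path.
#' @param body_mass_kg participant mass; defaults to the mass stored by the
#'   package writer when present.
#' @param ap_axis,ml_axis lab axes carrying the AP and ML coordinates
#'   (`"x"`, `"y"`, or `"z"`); configuration, never auto-detected.
#' @param condition_id identifier for the recording.
#' @return list with `recording` and `markers`, as [read_recording_csv()].
#' @export
read_recording_c3d <- function(path, body_mass_kg = NULL,
                               ap_axis = "y", ml_axis = "x",
                               condition_id = NA_character_) {
  if (!file.exists(path)) format_error(sprintf("file not found: %s", path))
  raw_data <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw_data) < 1024 || as.integer(raw_data[2]) != 80)
    unsupported_file_error("not a C3D file (bad magic byte)")
  rd16 <- function(i) readBin(raw_data[i:(i + 1L)], "integer", size = 2,
                              endian = "little")
  rdf <- function(i) readBin(raw_data[i:(i + 3L)], "numeric", size = 4,
                             endian = "little")
  param_block <- as.integer(raw_data[1])
  n_pts <- rd16(3L)
  analog_per_frame <- rd16(5L)
  first_frame <- rd16(7L)
  last_frame <- rd16(9L)
  scale <- rdf(13L)
  data_block <- rd16(17L)
  ratio <- rd16(19L)
  fs_m <- rdf(21L)
  if (scale >= 0)
    unsupported_file_error("only floating-point C3D data is supported")
  n_frames <- last_frame - first_frame + 1L
  params <- read_c3d_params(raw_data, (param_block - 1L) * 512L + 1L)
  point_labels <- params[["1:LABELS"]]
  analog_labels <- params[["2:LABELS"]]
  n_analog <- if (ratio > 0) analog_per_frame / ratio else 0L
  fs_f <- if (!is.null(params[["2:RATE"]])) params[["2:RATE"]] else fs_m * ratio

  fy <- grep("^FY[0-9]$", analog_labels, value = TRUE)
  if (length(fy) < 2)
    unsupported_file_error(sprintf(
      "need 2 force platforms (AP channels FY1/FY2); found %d", length(fy)))
  missing <- setdiff(unname(c3d_marker_label), point_labels)
  if (length(missing))
    format_error(paste0("required markers absent from C3D: ",
                        paste(missing, collapse = ", ")))

  vals <- readBin(raw_data[((data_block - 1L) * 512L + 1L):length(raw_data)],
                  "numeric", size = 4, endian = "little",
                  n = n_frames * (4L * n_pts + analog_per_frame))
  frame_len <- 4L * n_pts + analog_per_frame
  mat <- matrix(vals, nrow = frame_len)
  axis_row <- c(x = 1L, y = 2L, z = 3L)
  pt_idx <- function(lbl, axis) (match(lbl, point_labels) - 1L) * 4L + axis_row[[axis]]
  ap <- list(); ml <- list()
  for (nm in names(c3d_marker_label)) {
    lbl <- c3d_marker_label[[nm]]
    ap[[nm]] <- mat[pt_idx(lbl, ap_axis), ]
    ml[[nm]] <- mat[pt_idx(lbl, ml_axis), ]
  }
  an_base <- 4L * n_pts
  an_chan <- function(lbl) {
    j <- match(lbl, analog_labels)
    as.numeric(mat[an_base + seq(0L, ratio - 1L) * n_analog + j, ])
  }
  mass <- if (!is.null(body_mass_kg)) body_mass_kg
          else if (!is.null(params[["2:MASS"]])) params[["2:MASS"]]
          else format_error("body mass neither given nor stored in the file")
  rec <- grf_recording(an_chan("FY1"), an_chan("FY2"), fs_force = fs_f,
                       body_mass_kg = mass, condition_id = condition_id,
                       vertical_left = if ("FZ1" %in% analog_labels)
                         an_chan("FZ1") else NULL,
                       vertical_right = if ("FZ2" %in% analog_labels)
                         an_chan("FZ2") else NULL)
  mk <- marker_set(ap, ml, fs_marker = fs_m)
  list(recording = rec, markers = mk)
}
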