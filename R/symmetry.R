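#' Propulsion symmetry
#'
#' The relative contribution of the paretic leg (left leg for controls) to
#' total propulsion: `paretic / (paretic + non_paretic)`. Stored and modelled
#' as a fraction; 0.5 means both legs contribute equally, values below 0.5 a
#' smaller paretic contribution. Multiply by 100 for display as a percentage.
#'
#' @param paretic_value,nonparetic_value non-negative propulsion values
#'   (peak or impulse) for the paretic/reference and contralateral leg.
#' @return symmetry fraction in `[0, 1]`, or `NA` when both inputs are zero
#'   (undefined; the observation is dropped upstream with a logged reason).
#' @export
compute_symmetry <- function(paretic_value, nonparetic_value) {
  if (any(c(paretic_value, nonparetic_value) < 0, na.rm = TRUE))
    parameter_error("propulsion values must be non-negative")
  total <- paretic_value + nonparetic_value
  ifelse(total == 0, NA_real_, paretic_value / total)
}

#' Assemble the long-format observation table
#'
#' Builds the modelling table from per-condition summaries: one row per
#' participant, condition and leg, with legs relabelled to their role
#' (paretic / non-paretic for the stroke group, left / right for controls),
#' condition-level symmetry for both metrics, and the symmetry observed at
#' the comfortable-walking-speed (CWS) condition broadcast to all of a
#' participant's rows (it is the between-participant covariate of the
#' symmetry models). Participants whose CWS condition is missing or excluded
#' get `NA` symmetry-at-CWS and are thereby dropped from symmetry model fits;
#' their per-leg rows remain.
#'
#' @param per_participant list; each element a list with `participant_id`,
#'   `group`, `paretic_side`, `conditions` (row-bound per-leg summaries from
#'   [summarize_condition()] for the retained conditions).
#' @return data.frame with columns `participant_id`, `group`, `condition_id`,
#'   `speed`, `is_cws`, `leg`, `n_steps`, `peak`, `impulse`,
#'   `peak_symmetry`, `impulse_symmetry`, `peak_symmetry_at_cws`,
#'   `impulse_symmetry_at_cws`. Attribute `symmetry_dropped` lists
#'   participants without a usable CWS condition.
#' @export
build_observation_table <- function(per_participant) {
  dropped <- character(0)
  rows <- lapply(per_participant, function(p) {
    cond <- p$conditions
    if (is.null(cond) || !nrow(cond)) return(NULL)
    stroke <- identical(p$group, "stroke")
    cond$leg <- if (stroke) {
      ifelse(cond$leg == p$paretic_side, "paretic", "non_paretic")
    } else cond$leg
    ref <- if (stroke) "paretic" else "left"
    other <- if (stroke) "non_paretic" else "right"
    sym_of <- function(sub, metric) {
      a <- sub[[metric]][sub$leg == ref]
      b <- sub[[metric]][sub$leg == other]
      if (length(a) != 1L || length(b) != 1L) return(NA_real_)
      compute_symmetry(a, b)
    }
    split_cond <- split(cond, cond$condition_id)
    sym <- do.call(rbind, lapply(split_cond, function(sub) {
      data.frame(condition_id = sub$condition_id[1L],
                 peak_symmetry = sym_of(sub, "peak"),
                 impulse_symmetry = sym_of(sub, "impulse"),
                 stringsAsFactors = FALSE)
    }))
    cond <- merge(cond, sym, by = "condition_id", sort = FALSE)
    cws_rows <- cond[cond$is_cws, , drop = FALSE]
    if (!nrow(cws_rows) || all(is.na(cws_rows$peak_symmetry))) {
      dropped <<- c(dropped, p$participant_id)
      cond$peak_symmetry_at_cws <- NA_real_
      cond$impulse_symmetry_at_cws <- NA_real_
    } else {
      cond$peak_symmetry_at_cws <- cws_rows$peak_symmetry[1L]
      cond$impulse_symmetry_at_cws <- cws_rows$impulse_symmetry[1L]
    }
    cond$participant_id <- p$participant_id
    cond$group <- p$group
    cond
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  rownames(out) <- NULL
  cols <- c("participant_id", "group", "condition_id", "speed", "is_cws",
            "leg", "n_steps", "peak", "impulse", "peak_symmetry",
            "impulse_symmetry", "peak_symmetry_at_cws",
            "impulse_symmetry_at_cws")
  out <- out[, cols]
  attr(out, "symmetry_dropped") <- dropped
  out
}
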