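#' Default generator parameters
#'
#' Reads the parameter file shipped with the package
#' (`inst/extdata/params_study.yaml`), which carries a provenance comment for
#' every value: printed study estimates, values derived from printed
#' estimates in closed form, and package defaults for quantities the study
#' did not report.
#'
#' @param path optional path to an alternative YAML parameter file.
#' @return nested parameter list.
#' @export
default_params <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "params_study.yaml", package = "propulsr")
  if (!nzchar(path) || !file.exists(path))
    parameter_error("parameter file not found")
  yaml::read_yaml(path)
}

# Truncated-normal draw by resampling (bounds are loose, a few iterations).
rnorm_trunc <- function(n, mean, sd, lo, hi) {
  x <- rnorm(n, mean, sd)
  for (i in seq_len(50)) {
    bad <- x < lo | x > hi
    if (!any(bad)) break
    x[bad] <- rnorm(sum(bad), mean, sd)
  }
  pmin(hi, pmax(lo, x))
}


#' Sample a synthetic cohort with latent random effects
#'
#' Draws participant metadata (comfortable walking speed, body mass, paretic
#' side) and the per-participant latent effects of the generative mixed
#' model: intercept, speed-slope, leg, and speed-by-leg deviations for the
#' stroke group (slope and interaction deviations may be correlated);
#' intercept/slope plus independent per-leg deviations for controls
#' (exchangeable legs). All latents are zero-mean Gaussian with the
#' configured SDs.
#'
#' @param params parameter list from [default_params()].
#' @param group `"stroke"` or `"control"`.
#' @param seed optional integer seed (set before drawing when given).
#' @param n_participants override of the configured cohort size.
#' @return data.frame, one row per participant, metadata plus latent columns.
#' @export
sample_cohort <- function(params, group = c("stroke", "control"), seed = NULL,
                          n_participants = NULL) {
  group <- match.arg(group)
  if (!is.null(seed)) set.seed(seed)
  g <- params[[group]]
  n <- if (is.null(n_participants)) g$n_participants else n_participants
  if (n < 1) parameter_error("cohort size must be at least 1")
  for (m in c("peak", "impulse")) {
    for (f in c("sd_intercept", "sd_slope")) {
      if (g[[m]][[f]] < 0) parameter_error(sprintf("%s %s must be >= 0", m, f))
    }
  }
  cws <- round(rnorm_trunc(n, g$cws_mean, g$cws_sd, g$cws_min, g$cws_max), 1)
  mass <- rlnorm(n, log(g$mass_median_kg), g$mass_sdlog)
  out <- data.frame(
    participant_id = sprintf("%s%02d", if (group == "stroke") "S" else "C", seq_len(n)),
    group = group, cws = cws,
    max_speed = if (group == "stroke") round(cws + g$max_speed_margin, 1) else NA_real_,
    mass = mass,
    paretic_side = if (group == "stroke") {
      ifelse(runif(n) < g$paretic_left_ratio, "left", "right")
    } else "none",
    stringsAsFactors = FALSE)
  # cross-metric coupling: the peak and impulse latents of a participant
  # share standard-normal sources with correlation `cross_metric_corr`
  # (the same limb impairment drives both metrics); each metric's marginal
  # latent distribution is unchanged by this coupling
  xr <- if (is.null(g$cross_metric_corr)) 0 else g$cross_metric_corr
  z <- list(peak = matrix(rnorm(n * 4L), n))
  z$impulse <- xr * z$peak + sqrt(1 - xr^2) * matrix(rnorm(n * 4L), n)
  for (m in c("peak", "impulse")) {
    p <- g[[m]]
    zm <- z[[m]]
    out[[paste0(m, "_b0")]] <- p$sd_intercept * zm[, 1L]
    if (group == "stroke") {
      r13 <- p$corr_slope_interaction
      r23 <- p$corr_leg_interaction
      if (r13^2 + r23^2 > 1)
        parameter_error("latent correlations infeasible (rho13^2 + rho23^2 > 1)")
      out[[paste0(m, "_b1")]] <- p$sd_slope * zm[, 2L]
      out[[paste0(m, "_b2")]] <- p$sd_leg * zm[, 3L]
      out[[paste0(m, "_b3")]] <- p$sd_interaction *
        (r13 * zm[, 2L] + r23 * zm[, 3L] + sqrt(1 - r13^2 - r23^2) * zm[, 4L])
    } else {
      out[[paste0(m, "_b1")]] <- rnorm(n, 0, p$sd_slope)
      out[[paste0(m, "_dL0")]] <- rnorm(n, 0, p$sd_leg_intercept)
      out[[paste0(m, "_dR0")]] <- rnorm(n, 0, p$sd_leg_intercept)
      out[[paste0(m, "_dL1")]] <- rnorm(n, 0, p$sd_leg_slope)
      out[[paste0(m, "_dR1")]] <- rnorm(n, 0, p$sd_leg_slope)
    }
  }
  out
}

#' Build a participant's condition schedule
#'
#' Stroke protocol: speeds from 0.2 m/s up to and including the comfortable
#' walking speed (CWS) in 0.2 m/s increments, presented in randomized order,
#' then increasing from CWS in 0.1 m/s increments up to the participant's
#' maximum speed. Controls: 0.4 to 1.6 m/s in 0.2 m/s increments, randomized,
#' plus an additional condition at CWS. Durations follow
#' [condition_duration()].
#'
#' @param participant one row of a [sample_cohort()] data.frame.
#' @param randomize randomize the order of the base speed block (the
#'   analysis is order-independent; randomization only mirrors acquisition).
#' @return a [condition_schedule()].
#' @export
build_schedule <- function(participant, randomize = TRUE) {
  cws <- participant$cws
  if (cws < 0.2) parameter_error("comfortable walking speed below 0.2 m/s")
  if (participant$group == "stroke") {
    sub <- if (cws > 0.2 + 1e-9) seq(0.2, cws - 0.001, by = 0.2) else numeric(0)
    base <- round(c(sub[abs(sub - cws) > 1e-9], cws), 1)
    is_cws <- abs(base - cws) < 1e-9
    if (randomize) {
      ord <- sample.int(length(base))
      base <- base[ord]; is_cws <- is_cws[ord]
    }
    above <- if (participant$max_speed > cws + 0.05) {
      round(seq(cws + 0.1, participant$max_speed + 1e-9, by = 0.1), 1)
    } else numeric(0)
    speeds <- c(base, above)
    flags <- c(is_cws, rep(FALSE, length(above)))
  } else {
    base <- seq(0.4, 1.6, by = 0.2)
    if (randomize) base <- base[sample.int(length(base))]
    speeds <- c(base, cws)
    flags <- c(rep(FALSE, length(base)), TRUE)
  }
  condition_schedule(speeds, flags, group = participant$group,
                     paretic_side = participant$paretic_side, cws = cws,
                     condition_id = sprintf("%s_C%02d", participant$participant_id,
                                            seq_along(speeds)))
}

# Latent condition mean for one (participant, speed, leg role), before
# condition-level residual and truncation.
latent_mean <- function(participant, metric, speed, role) {
  g <- participant$group
  pm <- function(suffix) participant[[paste0(metric, "_", suffix)]]
  p <- attr(participant, "metric_params")[[metric]]
  if (g == "stroke") {
    is_p <- as.numeric(role == "paretic")
    (p$intercept + pm("b0")) + (p$slope + pm("b1")) * speed +
      is_p * ((p$leg_effect + pm("b2")) + (p$interaction + pm("b3")) * speed)
  } else {
    d0 <- if (role == "left") pm("dL0") else pm("dR0")
    d1 <- if (role == "left") pm("dL1") else pm("dR1")
    (p$intercept + pm("b0") + d0) + (p$slope + pm("b1") + d1) * speed
  }
}

#' Synthesize per-step propulsion metrics for one condition and leg
#'
#' The condition-level step mean is the generative mixed-model line
#' (fixed effects plus the participant's latents) plus a condition-level
#' residual; per-step values add between-step noise with a configured
#' coefficient of variation. Means and steps are floored at a small positive
#' value (a paretic limb can approach, but not produce, negative mean
#' propulsion); floored draws are counted in the ground truth. A configured
#' fraction of steps is flagged as crossover steps.
#'
#' @param participant one row of the cohort (with `metric_params` attribute
#'   attached by [generate_cohort()]).
#' @param condition one row of the participant's schedule.
#' @param leg `"left"` or `"right"` (anatomical side).
#' @param params full parameter list.
#' @return list with `steps` (data.frame) and `truth` (list of the latent
#'   line value, realized condition means, and injected crossover indices).
#' @export
synthesize_step_metrics <- function(participant, condition, leg, params) {
  g <- params[[participant$group]]
  role <- if (participant$group == "stroke") {
    if (leg == participant$paretic_side) "paretic" else "non_paretic"
  } else leg
  usable_s <- condition$duration_s - 15
  cad <- cadence_steps_per_min(condition$speed, params$cadence$intercept,
                               params$cadence$slope)
  n_steps <- max(0L, as.integer(floor(cad * usable_s / 60 / 2)))
  stance_s <- params$waveform$duty_factor * 120 / cad
  out <- list()
  truth <- list(condition_id = condition$condition_id, leg = leg, role = role)
  vals <- list()
  for (m in c("peak", "impulse")) {
    p <- g[[m]]
    line <- latent_mean(participant, m, condition$speed, role)
    mu <- line + rnorm(1, 0, p$sd_condition)
    floored_mean <- mu < p$floor
    mu <- max(p$floor, mu)
    step_vals <- rnorm(n_steps, mu, params$noise$step_cv * mu)
    n_floored <- sum(step_vals < p$floor)
    step_vals <- pmax(p$floor, step_vals)
    vals[[m]] <- step_vals
    truth[[paste0("line_", m)]] <- line
    truth[[paste0("mean_", m)]] <- mu
    truth[[paste0("floored_", m)]] <- n_floored + as.integer(floored_mean)
  }
  # physical consistency: a stance curve's area cannot exceed its peak times
  # the stance duration; cap the (independently drawn) impulse accordingly
  imp_max <- 0.85 * vals$peak * stance_s
  truth$capped_impulse <- sum(vals$impulse > imp_max)
  vals$impulse <- pmin(vals$impulse, imp_max)
  n_cross <- rbinom(1, n_steps, params$crossover_rate)
  cross_idx <- sort(sample.int(n_steps, n_cross))
  truth$crossover_steps <- cross_idx
  steps <- data.frame(
    participant_id = participant$participant_id,
    condition_id = condition$condition_id,
    speed = condition$speed, is_cws = condition$is_cws,
    leg = leg, step_index = seq_len(n_steps),
    peak = vals$peak, impulse = vals$impulse,
    crossover = seq_len(n_steps) %in% cross_idx,
    stringsAsFactors = FALSE)
  list(steps = steps, truth = truth)
}

#' Generate a full synthetic cohort dataset
#'
#' Runs cohort sampling, schedule construction and per-step synthesis for
#' every participant, condition and leg; in waveform mode each condition is
#' additionally rendered as 1000 Hz plate forces and 100 Hz marker
#' trajectories realizing the same per-step metrics. Fully reproducible:
#' identical `params` and `seed` give identical output.
#'
#' @param params parameter list from [default_params()].
#' @param group `"stroke"` or `"control"`.
#' @param seed integer seed.
#' @param mode `"metrics"` (per-step metrics only) or `"waveforms"`.
#' @param n_participants optional cohort-size override.
#' @return object of class `gait_dataset`: `participants`, `schedules`
#'   (named list), `steps` (one data.frame), `recordings` (waveform mode:
#'   named list of `list(recording, markers, events)` keyed by condition id),
#'   `truth` (list keyed by `condition_id/leg`), `params`, `seed`, `mode`.
#' @export
generate_cohort <- function(params, group = c("stroke", "control"), seed = 1L,
                            mode = c("metrics", "waveforms"),
                            n_participants = NULL) {
  group <- match.arg(group)
  mode <- match.arg(mode)
  set.seed(seed)
  cohort <- sample_cohort(params, group, seed = NULL,
                          n_participants = n_participants)
  schedules <- list()
  steps <- list()
  truth <- list()
  recordings <- list()
  for (i in seq_len(nrow(cohort))) {
    part <- cohort[i, , drop = FALSE]
    attr(part, "metric_params") <- params[[group]]
    sched <- build_schedule(part)
    schedules[[part$participant_id]] <- sched
    for (j in seq_len(nrow(sched))) {
      cond <- sched[j, , drop = FALSE]
      both <- lapply(c("left", "right"), function(lg)
        synthesize_step_metrics(part, cond, lg, params))
      for (b in both) {
        steps[[length(steps) + 1L]] <- b$steps
        truth[[paste0(b$truth$condition_id, "/", b$truth$leg)]] <- b$truth
      }
      if (mode == "waveforms") {
        recordings[[cond$condition_id]] <- synthesize_waveforms(
          steps_left = both[[1L]]$steps, steps_right = both[[2L]]$steps,
          condition = cond, mass = part$mass, params = params)
      }
    }
  }
  structure(list(participants = cohort, schedules = schedules,
                 steps = do.call(rbind, steps), recordings = recordings,
                 truth = truth, params = params, seed = seed,
                 group = group, mode = mode),
            class = "gait_dataset")
}

#' @export
print.gait_dataset <- function(x, ...) {
  cat(sprintf("<gait_dataset> %s cohort, n = %d, mode = %s, seed = %d, %d step records\n",
              x$group, nrow(x$participants), x$mode, x$seed, nrow(x$steps)))
  invisible(x)
}
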