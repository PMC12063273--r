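#' Process one waveform condition into per-step metrics
#'
#' The full signal pathway for a single condition: trim the start/stop
#' phases, low-pass filter force and marker channels (same 15 Hz zero-phase
#' spec), resample force to the marker rate, detect stance phases from the
#' foot markers, flag crossover steps, and extract mass-normalized
#' propulsion peak and impulse per stance.
#'
#' @param recording a [grf_recording()] covering the whole condition.
#' @param markers the matching [marker_set()].
#' @param speed belt speed in m/s.
#' @param spec filter specification, default [filter_spec()].
#' @param head_s,tail_s trim durations in seconds.
#' @param belt_midline ML coordinate of the belt gap.
#' @param cadence_model cadence model passed to [detect_stance_phases()].
#' @return data.frame of per-step metrics (leg, step_index, ic_index,
#'   tc_index, peak, impulse, bridged_dips, valid, reason) at the marker
#'   rate's index base, steady-state window only.
#' @export
process_recording <- function(recording, markers, speed,
                              spec = filter_spec(), head_s = 10, tail_s = 5,
                              belt_midline = 0, cadence_model = c(60, 40)) {
  tr <- trim_condition(recording, markers, head_s = head_s, tail_s = tail_s)
  rec <- tr$recording
  mk <- tr$markers
  fs_f <- rec$fs_force
  fs_m <- mk$fs_marker
  ap_filt <- lapply(rec$ap, filter_zero_phase, fs = fs_f, spec = spec)
  mk$ap <- lapply(mk$ap, filter_zero_phase, fs = fs_m, spec = spec)
  ap_100 <- lapply(ap_filt, resample_series, fs_in = fs_f, fs_out = fs_m)
  phases <- detect_stance_phases(mk, belt_speed = speed,
                                 cadence_model = cadence_model)
  phases <- flag_crossover_steps(phases, mk, belt_midline = belt_midline)
  extract_step_metrics(ap_100, phases, fs = fs_m,
                       body_mass_kg = rec$body_mass_kg)
}

#' Process a synthetic dataset into the observation table
#'
#' Applies the full analysis chain to a [generate_cohort()] dataset. In
#' metrics mode the generated per-step metrics are summarized directly
#' (crossover-injected steps excluded); in waveform mode every condition is
#' first run through [process_recording()]. Conditions with fewer than
#' `min_steps` valid steps on either leg are dropped; participants with two
#' or more such conditions are excluded entirely.
#'
#' @param dataset a `gait_dataset`.
#' @param min_steps minimum valid steps per leg per condition (default 23).
#' @param max_failed maximum failing conditions for a retained participant.
#' @param spec filter spec for waveform mode.
#' @return list with `observations` (the long-format modelling table),
#'   `excluded_participants`, `exclusion_report` (one row per participant
#'   and condition), `symmetry_dropped` (participants lacking a usable CWS
#'   condition), and `step_counts` (valid steps per condition and leg).
#' @export
process_dataset <- function(dataset, min_steps = 23L, max_failed = 1L,
                            spec = filter_spec()) {
  per_participant <- list()
  reports <- list()
  excluded <- character(0)
  counts <- list()
  for (i in seq_len(nrow(dataset$participants))) {
    part <- dataset$participants[i, , drop = FALSE]
    sched <- dataset$schedules[[part$participant_id]]
    cond_list <- list()
    for (j in seq_len(nrow(sched))) {
      cond <- sched[j, , drop = FALSE]
      if (dataset$mode == "metrics") {
        st <- dataset$steps[dataset$steps$condition_id == cond$condition_id, ,
                            drop = FALSE]
        st$valid <- !st$crossover
        st$reason <- ifelse(st$crossover, "crossover", "none")
      } else {
        rc <- dataset$recordings[[cond$condition_id]]
        st <- process_recording(rc$recording, rc$markers, speed = cond$speed,
                                spec = spec,
                                cadence_model = c(dataset$params$cadence$intercept,
                                                  dataset$params$cadence$slope))
      }
      cs <- summarize_condition(st, speed = cond$speed,
                                condition_id = cond$condition_id,
                                is_cws = cond$is_cws, min_steps = min_steps)
      cond_list[[j]] <- cs
      counts[[length(counts) + 1L]] <- data.frame(
        participant_id = part$participant_id,
        condition_id = cond$condition_id, leg = cs$leg,
        n_steps = cs$n_steps, stringsAsFactors = FALSE)
    }
    dec <- apply_participant_exclusion(cond_list, max_failed = max_failed)
    dec$report$participant_id <- part$participant_id
    dec$report$participant_kept <- dec$include_participant
    reports[[i]] <- dec$report
    if (!dec$include_participant) {
      excluded <- c(excluded, part$participant_id)
      next
    }
    per_participant[[length(per_participant) + 1L]] <- list(
      participant_id = part$participant_id, group = part$group,
      paretic_side = part$paretic_side, conditions = dec$kept)
  }
  if (!length(per_participant))
    parameter_error("all participants excluded; nothing to analyse")
  obs <- build_observation_table(per_participant)
  list(observations = obs,
       excluded_participants = excluded,
       exclusion_report = do.call(rbind, reports),
       symmetry_dropped = attr(obs, "symmetry_dropped"),
       step_counts = do.call(rbind, counts))
}

#' Fit the full model suite on an observation table
#'
#' Fits the primary symmetry models (peak and impulse, per group present in
#' the table), the per-leg speed-by-leg models for the stroke group, the
#' control absolute-propulsion models, and — when a speed-by-leg interaction
#' is significant at `alpha` — the per-leg post-hoc fits. Non-convergence is
#' surfaced per model; the suite continues.
#'
#' @param obs observation table from [process_dataset()].
#' @param df_method degrees-of-freedom method for reported p-values.
#' @param alpha significance level gating the post-hoc fits.
#' @return named list of `lmm_fit` objects (entries `NULL` when a model's
#'   group is absent); attribute `errors` collects per-model failures.
#' @export
fit_model_suite <- function(obs, df_method = "kenward-roger", alpha = 0.05) {
  fits <- list()
  errs <- list()
  try_fit <- function(name, expr) {
    fits[[name]] <<- tryCatch(expr, error = function(e) {
      errs[[name]] <<- conditionMessage(e)
      NULL
    })
  }
  groups <- unique(obs$group)
  for (metric in c("peak", "impulse")) {
    if ("stroke" %in% groups) {
      try_fit(paste0("symmetry_", metric, "_stroke"),
              fit_symmetry_model(obs, metric, "stroke", df_method))
      try_fit(paste0("leg_", metric),
              fit_leg_model(obs, metric, df_method))
      lf <- fits[[paste0("leg_", metric)]]
      if (!is.null(lf)) {
        pint <- lf$fixed$p[lf$fixed$term == "speed:leg_paretic"]
        if (is.finite(pint) && pint < alpha) {
          try_fit(paste0("posthoc_", metric, "_non_paretic"),
                  fit_per_leg_posthoc(obs, metric, "non_paretic", df_method))
          try_fit(paste0("posthoc_", metric, "_paretic"),
                  fit_per_leg_posthoc(obs, metric, "paretic", df_method))
        }
      }
    }
    if ("control" %in% groups) {
      try_fit(paste0("symmetry_", metric, "_control"),
              fit_symmetry_model(obs, metric, "control", df_method))
      try_fit(paste0("control_", metric),
              fit_control_metric_model(obs, metric, df_method))
    }
  }
  attr(fits, "errors") <- errs
  fits
}

run_config_defaults <- function() {
  list(outdir = "results", seed = 1L, mode = "metrics",
       params_file = NULL, df_method = "kenward-roger",
       min_steps = 23L, max_failed = 1L, alpha = 0.05,
       groups = c("stroke", "control"))
}

#' Load a run configuration
#'
#' @param path YAML file with any subset of the run-configuration fields
#'   (`outdir`, `seed`, `mode`, `params_file`, `df_method`, `min_steps`,
#'   `max_failed`, `alpha`, `groups`); missing fields take package defaults.
#' @return run-configuration list.
#' @export
load_run_config <- function(path = NULL) {
  cfg <- run_config_defaults()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg[names(user)] <- user
  }
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(paste(deparse(cfg[order(names(cfg))]), collapse = ""), f)
  unname(tools::md5sum(f))
}

#' Generate a synthetic study dataset on disk
#'
#' Writes per-step metrics, participant metadata, schedules, ground truth
#' and a provenance manifest (seed, parameter hash) under `cfg$outdir`.
#'
#' @param cfg run configuration from [load_run_config()].
#' @return (invisibly) the list of generated `gait_dataset`s by group.
#' @export
run_generate <- function(cfg = load_run_config()) {
  params <- default_params(cfg$params_file)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  datasets <- list()
  for (grp in cfg$groups) {
    ds <- generate_cohort(params, group = grp,
                          seed = child_seed(cfg$seed, match(grp, c("stroke", "control"))),
                          mode = cfg$mode)
    datasets[[grp]] <- ds
    write.csv(ds$steps, file.path(cfg$outdir, paste0("steps_", grp, ".csv")),
              row.names = FALSE)
    write.csv(ds$participants,
              file.path(cfg$outdir, paste0("participants_", grp, ".csv")),
              row.names = FALSE)
    sched <- do.call(rbind, lapply(names(ds$schedules), function(pid) {
      s <- as.data.frame(ds$schedules[[pid]])
      s$participant_id <- pid
      s
    }))
    write.csv(sched, file.path(cfg$outdir, paste0("schedules_", grp, ".csv")),
              row.names = FALSE)
    jsonlite::write_json(ds$truth,
                         file.path(cfg$outdir, paste0("truth_", grp, ".json")),
                         auto_unbox = TRUE, digits = NA)
  }
  manifest <- list(seed = cfg$seed, mode = cfg$mode,
                   groups = cfg$groups, config_hash = config_hash(cfg),
                   n_participants = lapply(datasets, function(d) nrow(d$participants)))
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(datasets)
}

#' Process generated datasets into the observation table
#'
#' Runs [process_dataset()] for every group and writes the combined
#' observation table, the per-step audit trail, and the exclusion report.
#'
#' @param cfg run configuration.
#' @param datasets optional in-memory datasets from [run_generate()] (else
#'   regenerated deterministically from the seed).
#' @return (invisibly) the combined observation table.
#' @export
run_process <- function(cfg = load_run_config(), datasets = NULL) {
  if (is.null(datasets)) datasets <- run_generate(cfg)
  obs <- list()
  reports <- list()
  audits <- list()
  for (grp in names(datasets)) {
    res <- process_dataset(datasets[[grp]], min_steps = cfg$min_steps,
                           max_failed = cfg$max_failed)
    obs[[grp]] <- res$observations
    rep <- res$exclusion_report
    rep$group <- grp
    reports[[grp]] <- rep
    audits[[grp]] <- res$step_counts
    message(sprintf(
      "[process] %s: %d participants kept, %d excluded, %d symmetry-dropped",
      grp, length(unique(res$observations$participant_id)),
      length(res$excluded_participants), length(res$symmetry_dropped)))
  }
  all_obs <- do.call(rbind, obs)
  rownames(all_obs) <- NULL
  write_observation_table(all_obs, file.path(cfg$outdir, "observations.csv"))
  write.csv(do.call(rbind, reports),
            file.path(cfg$outdir, "exclusion_report.csv"), row.names = FALSE)
  write.csv(do.call(rbind, audits),
            file.path(cfg$outdir, "step_audit.csv"), row.names = FALSE)
  invisible(all_obs)
}

#' Fit and export the model suite
#'
#' @param cfg run configuration.
#' @param obs optional in-memory observation table (else read from
#'   `cfg$outdir/observations.csv`).
#' @return (invisibly) the list of fits.
#' @export
run_model <- function(cfg = load_run_config(), obs = NULL) {
  if (is.null(obs))
    obs <- read_observation_table(file.path(cfg$outdir, "observations.csv"))
  fits <- fit_model_suite(obs, df_method = cfg$df_method, alpha = cfg$alpha)
  keep <- !vapply(fits, is.null, TRUE)
  jsonlite::write_json(lapply(fits[keep], lmm_fit_to_list),
                       file.path(cfg$outdir, "model_fits.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  report <- unlist(lapply(names(fits)[keep], function(nm) {
    f <- fits[[nm]]
    fx <- f$fixed[f$fixed$reported, , drop = FALSE]
    c(sprintf("== %s (%s)", nm, f$formula),
      sprintf("   %-18s beta = %8.4g  SE = %.3g  t = %.3g(%.1f)  p = %.3g",
              fx$term, fx$estimate, fx$se, fx$t, fx$df, fx$p),
      sprintf("   random SDs: %s; residual %.3g%s",
              paste(sprintf("%s %.3g", f$ranef_sd$term, f$ranef_sd$sd),
                    collapse = ", "),
              f$residual_sd,
              if (f$singular) " [singular fit]" else ""))
  }))
  writeLines(report, file.path(cfg$outdir, "model_report.txt"))
  invisible(fits)
}
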