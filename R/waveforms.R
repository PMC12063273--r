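# Two-lobe stance template: a negative (braking) half-sine in early stance
# followed by a positive (propulsive) lobe in late stance. The propulsion
# lobe's amplitude and duration solve the step's target peak and impulse in
# closed form: amplitude A = peak, duration T = pi * impulse / (2 * peak),
# since a half-sine of amplitude A and duration T has area 2 A T / pi. When
# that half-sine is wider than the stance allows (slow paretic steps with a
# low peak but preserved impulse), the lobe flattens into a
# quarter-sine / plateau / quarter-sine shape of the same peak and area;
# the braking lobe is dropped when the propulsion lobe needs its room.
# Optional atypical features for window-rule testing: an interior negative
# dip carved into the propulsion lobe, and a trailing negative lobe after it.

#' Render one stance phase of AP-GRF
#'
#' @param peak_n propulsion peak in N (positive).
#' @param impulse_ns propulsion impulse in N.s (positive).
#' @param stance_s stance duration in seconds.
#' @param fs sampling rate in Hz.
#' @param braking_peak_ratio braking amplitude as a fraction of `peak_n`.
#' @param braking_onset,braking_duration braking lobe placement as fractions
#'   of stance (the braking lobe is shortened if the propulsion lobe needs
#'   the room).
#' @param propulsion_end_margin gap between propulsion end and terminal
#'   contact, as a fraction of stance.
#' @param interior_dip optional `list(depth_n, duration_s)`: a negative dip
#'   splitting the propulsion lobe (its area subtracts from the impulse).
#' @param trailing_lobe optional `list(amplitude_n, duration_s)`: a negative
#'   lobe after the propulsion lobe (excluded from the impulse by the
#'   window rule).
#' @return numeric vector of `round(stance_s * fs)` force samples (N).
#' @export
render_stance_curve <- function(peak_n, impulse_ns, stance_s, fs,
                                braking_peak_ratio = 0.9,
                                braking_onset = 0.05,
                                braking_duration = 0.30,
                                propulsion_end_margin = 0.04,
                                interior_dip = NULL,
                                trailing_lobe = NULL) {
  assert_scalar_positive(peak_n, "peak_n")
  assert_scalar_positive(impulse_ns, "impulse_ns")
  m <- as.integer(round(stance_s * fs))
  t <- (seq_len(m) - 1) / fs
  x <- numeric(m)
  min_gap <- 0.02 * stance_s
  prop_end <- (1 - propulsion_end_margin) * stance_s
  avail <- prop_end - min_gap
  half_T <- pi * impulse_ns / (2 * peak_n)
  if (half_T <= avail) {
    prop_T <- half_T
    prop_start <- prop_end - prop_T
    in_prop <- t >= prop_start & t <= prop_end
    x[in_prop] <- peak_n * sin(pi * (t[in_prop] - prop_start) / prop_T)
  } else {
    # plateau lobe: quarter-sine rise (r), plateau (d) at peak, quarter-sine
    # fall (r); area = A * (d + 4 r / pi), solved for the target impulse at
    # the maximum available width
    width <- avail
    r <- (width - impulse_ns / peak_n) / (2 * (1 - 2 / pi))
    if (r < 0 || impulse_ns / peak_n > 0.98 * width)
      parameter_error(sprintf(
        "propulsion lobe does not fit a %.3f s stance (peak %.1f N, impulse %.3f N.s)",
        stance_s, peak_n, impulse_ns))
    d <- width - 2 * r
    prop_start <- prop_end - width
    seg <- t - prop_start
    in_rise <- seg >= 0 & seg < r
    in_flat <- seg >= r & seg <= r + d
    in_fall <- seg > r + d & seg <= width
    x[in_rise] <- peak_n * sin(pi * seg[in_rise] / (2 * r))
    x[in_flat] <- peak_n
    x[in_fall] <- peak_n * sin(pi * (width - seg[in_fall]) / (2 * r))
  }
  brk_start <- braking_onset * stance_s
  brk_end <- min((braking_onset + braking_duration) * stance_s,
                 prop_start - min_gap)
  if (brk_end - brk_start > 0.03 * stance_s) {
    in_brk <- t >= brk_start & t <= brk_end
    x[in_brk] <- -braking_peak_ratio * peak_n *
      sin(pi * (t[in_brk] - brk_start) / (brk_end - brk_start))
  }
  if (!is.null(interior_dip)) {
    dip_mid <- prop_start + prop_T / 2
    d0 <- dip_mid - interior_dip$duration_s / 2
    d1 <- dip_mid + interior_dip$duration_s / 2
    in_dip <- t >= d0 & t <= d1
    x[in_dip] <- -interior_dip$depth_n *
      sin(pi * (t[in_dip] - d0) / (d1 - d0))
  }
  if (!is.null(trailing_lobe)) {
    t0 <- prop_end + min_gap
    t1 <- min(t0 + trailing_lobe$duration_s, stance_s * 0.999)
    in_tr <- t > t0 & t <= t1
    x[in_tr] <- -trailing_lobe$amplitude_n *
      sin(pi * (t[in_tr] - t0) / (t1 - t0))
  }
  x
}

# Pelvis-relative AP trajectory of one foot over the condition: linear
# backward travel at belt speed during stance, half-cosine forward return
# during swing. Rendered from virtual step indices extending past both ends
# so the trajectory is smooth across the analysis window.
foot_ap_trajectory <- function(n, fs, ic_times, stride_s, stance_s, speed) {
  t <- (seq_len(n) - 1) / fs
  x_ic <- speed * stance_s / 2
  x_tc <- -speed * stance_s / 2
  swing_s <- stride_s - stance_s
  x <- numeric(n)
  # extend with virtual steps so every sample falls in some stride
  all_ics <- c(ic_times[1] - (3:1) * stride_s, ic_times,
               ic_times[length(ic_times)] + (1:3) * stride_s)
  for (ic in all_ics) {
    in_st <- t >= ic & t < ic + stance_s
    x[in_st] <- x_ic - speed * (t[in_st] - ic)
    in_sw <- t >= ic + stance_s & t < ic + stride_s
    ph <- (t[in_sw] - ic - stance_s) / swing_s
    x[in_sw] <- x_tc + (x_ic - x_tc) * (1 - cos(pi * ph)) / 2
  }
  x
}

#' Render plate forces and marker trajectories for one condition
#'
#' Realizes a condition's per-step metrics as a two-half-sine AP-GRF per
#' stance on the leg's own plate (1000 Hz) plus heel/toe/pelvis marker
#' trajectories (100 Hz) whose pelvis-relative extrema encode the initial
#' and terminal contacts. Mediolateral coordinates place each foot on its
#' own belt except for injected crossover steps, during which the
#' contralateral foot crosses the belt midline. Steps are laid out inside
#' the steady-state window (after the 10 s start phase, before the 5 s stop
#' phase); steps that would overrun the recording are not rendered.
#'
#' @param steps_left,steps_right per-step metrics from
#'   [synthesize_step_metrics()] (N/kg units).
#' @param condition one schedule row.
#' @param mass participant body mass (kg).
#' @param params full parameter list.
#' @return list with `recording` ([grf_recording()]), `markers`
#'   ([marker_set()]), and `events` (data.frame of rendered ground-truth
#'   `leg`, `step_index`, `ic_s`, `tc_s` in seconds from condition start).
#' @export
synthesize_waveforms <- function(steps_left, steps_right, condition, mass,
                                 params) {
  wf <- params$waveform
  fs_f <- 1000
  fs_m <- 100
  dur <- condition$duration_s
  v <- condition$speed
  cad <- cadence_steps_per_min(v, params$cadence$intercept, params$cadence$slope)
  stride_s <- 120 / cad
  stance_s <- wf$duty_factor * stride_s
  n_f <- as.integer(dur * fs_f)
  n_m <- as.integer(dur * fs_m)
  force <- list(left = numeric(n_f), right = numeric(n_f))
  vert <- list(left = numeric(n_f), right = numeric(n_f))
  events <- list()
  ml <- list(heel_left = rep(-wf$belt_offset_m, n_m),
             toe_left = rep(-wf$belt_offset_m, n_m),
             heel_right = rep(wf$belt_offset_m, n_m),
             toe_right = rep(wf$belt_offset_m, n_m),
             pelvis = rep(0, n_m))

  for (lg in c("left", "right")) {
    steps <- if (lg == "left") steps_left else steps_right
    t0 <- 10.5 + if (lg == "right") stride_s / 2 else 0
    ic_times <- t0 + (steps$step_index - 1) * stride_s
    rendered <- ic_times + stance_s <= dur - 0.2
    for (k in which(rendered)) {
      curve <- render_stance_curve(
        peak_n = steps$peak[k] * mass, impulse_ns = steps$impulse[k] * mass,
        stance_s = stance_s, fs = fs_f,
        braking_peak_ratio = wf$braking_peak_ratio,
        braking_onset = wf$braking_onset,
        braking_duration = wf$braking_duration,
        propulsion_end_margin = wf$propulsion_end_margin)
      i0 <- as.integer(round(ic_times[k] * fs_f))
      idx <- i0 + seq_along(curve)
      force[[lg]][idx] <- force[[lg]][idx] + curve
      vert[[lg]][idx] <- vert[[lg]][idx] + mass * 9.81
      events[[length(events) + 1L]] <- data.frame(
        leg = lg, step_index = steps$step_index[k],
        ic_s = ic_times[k], tc_s = ic_times[k] + stance_s,
        crossover = steps$crossover[k], stringsAsFactors = FALSE)
    }
    ap <- foot_ap_trajectory(n_m, fs_m, ic_times[rendered], stride_s,
                             stance_s, v)
    ml_self <- if (lg == "left") -wf$belt_offset_m else wf$belt_offset_m
    contra <- if (lg == "left") "right" else "left"
    # injected crossover: the contralateral foot crosses the midline during
    # this leg's stance
    for (k in which(rendered & steps$crossover)) {
      j0 <- as.integer(round(ic_times[k] * fs_m)) + 1L
      j1 <- as.integer(round((ic_times[k] + stance_s) * fs_m))
      jj <- max(1L, j0):min(n_m, j1)
      cross_ml <- if (lg == "left") abs(wf$crossover_ml_m) * -1 else
        abs(wf$crossover_ml_m)
      ml[[paste0("heel_", contra)]][jj] <- cross_ml
      ml[[paste0("toe_", contra)]][jj] <- cross_ml
    }
    assign(paste0("ap_", lg), ap)
  }

  markers <- marker_set(
    ap = list(heel_left = ap_left, toe_left = ap_left + wf$foot_length_m,
              heel_right = ap_right, toe_right = ap_right + wf$foot_length_m,
              pelvis = rep(0, n_m)),
    ml = ml, fs_marker = fs_m)
  recording <- grf_recording(force$left, force$right, fs_force = fs_f,
                             body_mass_kg = mass,
                             condition_id = condition$condition_id,
                             vertical_left = vert$left,
                             vertical_right = vert$right)
  list(recording = recording, markers = markers,
       events = do.call(rbind, events))
}
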