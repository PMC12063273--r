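test_that("latent effects have the configured spread, vanish at SD zero, and reproduce", {
  p <- default_params()
  big <- sample_cohort(p, "stroke", seed = 5, n_participants = 10000)
  expect_lt(abs(sd(big$peak_b1) - 0.43) / 0.43, 0.02)
  expect_lt(abs(sd(big$impulse_b1) - 0.070) / 0.070, 0.02)
  expect_lt(abs(sd(big$impulse_b3) - 0.071) / 0.071, 0.03)
  # configured latent correlations are realized
  expect_lt(abs(cor(big$peak_b1, big$peak_b3) - (-0.68)), 0.03)
  expect_lt(abs(cor(big$impulse_b2, big$impulse_b3) - (-0.72)), 0.03)

  p0 <- p
  for (f in c("sd_intercept", "sd_slope", "sd_leg", "sd_interaction"))
    p0$stroke$peak[[f]] <- 0
  zero <- sample_cohort(p0, "stroke", seed = 5, n_participants = 50)
  expect_true(all(zero$peak_b0 == 0 & zero$peak_b1 == 0 &
                    zero$peak_b2 == 0 & zero$peak_b3 == 0))

  a <- sample_cohort(p, "stroke", seed = 42)
  b <- sample_cohort(p, "stroke", seed = 42)
  expect_identical(a, b)
})

test_that("schedules follow the acquisition protocol", {
  part <- data.frame(participant_id = "S01", group = "stroke", cws = 0.8,
                     max_speed = 1.0, mass = 80, paretic_side = "left",
                     stringsAsFactors = FALSE)
  set.seed(1)
  s <- build_schedule(part)
  expect_equal(sort(s$speed), c(0.2, 0.4, 0.6, 0.8, 0.9, 1.0), tolerance = 1e-9)
  expect_equal(s$speed[s$is_cws], 0.8)
  expect_equal(sort(s$duration_s[s$speed <= 0.4]), rep(180, 2))
  expect_true(all(s$duration_s[s$speed > 0.4] == 120))

  ctrl <- data.frame(participant_id = "C01", group = "control", cws = 1.3,
                     max_speed = NA_real_, mass = 70, paretic_side = "none",
                     stringsAsFactors = FALSE)
  sc <- build_schedule(ctrl)
  expect_equal(nrow(sc), 8)  # 0.4-1.6 by 0.2 plus the CWS condition
  expect_equal(sort(sc$speed[!sc$is_cws]), seq(0.4, 1.6, 0.2), tolerance = 1e-9)
  expect_equal(sc$speed[sc$is_cws], 1.3)

  part$cws <- 0.2; part$max_speed <- 0.2
  s02 <- build_schedule(part)
  expect_equal(nrow(s02), 1)
  part$cws <- 0.1
  expect_error(build_schedule(part), class = "propulsr_parameter_error")
})

test_that("with zero noise and zero latents, steps sit exactly on the fixed-effect line", {
  p <- default_params()
  for (m in c("peak", "impulse")) {
    for (f in c("sd_intercept", "sd_slope", "sd_leg", "sd_interaction",
                "sd_condition"))
      p$stroke[[m]][[f]] <- 0
  }
  p$noise$step_cv <- 0
  p$crossover_rate <- 0
  ds <- generate_cohort(p, "stroke", seed = 3, n_participants = 2)
  part <- ds$participants[1, ]
  sched <- ds$schedules[[part$participant_id]]
  cfgs <- p$stroke
  for (j in seq_len(nrow(sched))) {
    v <- sched$speed[j]
    st <- ds$steps[ds$steps$condition_id == sched$condition_id[j], ]
    np_leg <- setdiff(c("left", "right"), part$paretic_side)
    expect_equal(unique(st$peak[st$leg == np_leg]),
                 cfgs$peak$intercept + cfgs$peak$slope * v, tolerance = 1e-12)
    expect_equal(unique(st$peak[st$leg == part$paretic_side]),
                 cfgs$peak$intercept + cfgs$peak$leg_effect +
                   (cfgs$peak$slope + cfgs$peak$interaction) * v,
                 tolerance = 1e-12)
  }
})

test_that("step counts follow the cadence model and the trim arithmetic", {
  p <- default_params()
  p$crossover_rate <- 0
  ds <- generate_cohort(p, "stroke", seed = 13, n_participants = 3)
  sched <- do.call(rbind, unname(lapply(ds$schedules, as.data.frame)))
  for (j in seq_len(nrow(sched))) {
    st <- ds$steps[ds$steps$condition_id == sched$condition_id[j] &
                     ds$steps$leg == "left", ]
    cad <- 60 + 40 * sched$speed[j]
    expected <- floor(cad * (sched$duration_s[j] - 15) / 60 / 2)
    expect_equal(nrow(st), expected)
  }
  # every standard condition clears the 23-step threshold by design
  counts <- table(ds$steps$condition_id, ds$steps$leg)
  expect_true(all(counts >= 23))
})

test_that("generated control peaks regress on speed at the configured slope", {
  p <- default_params()
  ds <- generate_cohort(p, "control", seed = 17, mode = "metrics",
                        n_participants = 200)
  obs <- process_dataset(ds)$observations
  ols <- coef(lm(peak ~ speed, data = obs))[["speed"]]
  expect_lt(abs(ols - 1.73) / 1.73, 0.02)
})

test_that("generation is bit-identical for identical params and seed", {
  p <- fast_params()
  d1 <- generate_cohort(p, "stroke", seed = 99)
  d2 <- generate_cohort(p, "stroke", seed = 99)
  expect_identical(d1$steps, d2$steps)
  expect_identical(d1$participants, d2$participants)
  d3 <- generate_cohort(p, "stroke", seed = 100)
  expect_false(identical(d1$steps, d3$steps))
})

test_that("rendered waveforms realize the requested peak exactly", {
  curve <- render_stance_curve(peak_n = 1.5 * 80, impulse_ns = 0.25 * 80,
                               stance_s = 0.8, fs = 1000)
  expect_equal(max(curve), 120, tolerance = 1e-5)
  # closed-form area: trapezoid of the rendered lobe matches the target
  expect_equal(trapz_series(pmax(curve, 0), 1000), 0.25 * 80,
               tolerance = 0.25 * 80 * 0.005)
  expect_error(render_stance_curve(5, 100, 0.6, 1000),
               class = "propulsr_parameter_error")
})

test_that("the full pipeline recovers injected per-step metrics through the waveform route", {
  p <- default_params()
  p$stroke$n_participants <- 1
  p$stroke$cws_min <- 0.7; p$stroke$cws_max <- 0.7
  p$stroke$max_speed_margin <- 0
  p$noise$step_cv <- 0
  for (m in c("peak", "impulse")) p$stroke[[m]]$sd_condition <- 0
  p$crossover_rate <- 0
  ds <- generate_cohort(p, "stroke", seed = 23, mode = "waveforms")
  sched <- ds$schedules[[1]]
  for (j in c(1, nrow(sched))) {
    cid <- sched$condition_id[j]
    rc <- ds$recordings[[cid]]
    st <- process_recording(rc$recording, rc$markers, speed = sched$speed[j])
    inj <- ds$steps[ds$steps$condition_id == cid, ]
    for (lg in c("left", "right")) {
      matched <- match_steps_to_events(st, rc$events, lg)
      expect_true(all(matched$dt <= 0.02))
      inj_lg <- inj[inj$leg == lg, ]
      rel_pk <- abs(matched$peak - inj_lg$peak[matched$truth_step]) /
        inj_lg$peak[matched$truth_step]
      rel_im <- abs(matched$impulse - inj_lg$impulse[matched$truth_step]) /
        inj_lg$impulse[matched$truth_step]
      expect_lt(stats::quantile(rel_pk, 0.95), 0.02)
      expect_lt(stats::quantile(rel_im, 0.95), 0.02)
    }
  }
})

test_that("waveform-mode and metrics-mode condition means agree per cell", {
  p <- default_params()
  p$stroke$n_participants <- 2
  p$stroke$cws_min <- 0.7; p$stroke$cws_max <- 0.9
  p$stroke$max_speed_margin <- 0.1
  ds_w <- generate_cohort(p, "stroke", seed = 37, mode = "waveforms")
  ds_m <- generate_cohort(p, "stroke", seed = 37, mode = "metrics")
  expect_identical(ds_w$steps, ds_m$steps)  # same draws, same seed
  obs_w <- process_dataset(ds_w)$observations
  obs_m <- process_dataset(ds_m)$observations
  key <- function(d) paste(d$condition_id, d$leg)
  common <- intersect(key(obs_w), key(obs_m))
  iw <- match(common, key(obs_w)); im <- match(common, key(obs_m))
  expect_true(all(abs(obs_w$peak[iw] - obs_m$peak[im]) / obs_m$peak[im] < 0.02))
  expect_true(all(abs(obs_w$impulse[iw] - obs_m$impulse[im]) /
                    obs_m$impulse[im] < 0.02))
})
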