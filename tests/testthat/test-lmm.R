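# Small shared observation tables for the model-fitting tests.
obs_stroke <- local({
  p <- default_params()
  ds <- generate_cohort(p, "stroke", seed = 201, mode = "metrics")
  process_dataset(ds)$observations
})
obs_control <- local({
  p <- default_params()
  ds <- generate_cohort(p, "control", seed = 202, mode = "metrics")
  process_dataset(ds)$observations
})

test_that("model fits expose estimates, SEs, df, p, and random-effect SDs", {
  f <- fit_symmetry_model(obs_stroke, "impulse", "stroke",
                          df_method = "satterthwaite")
  expect_s3_class(f, "lmm_fit")
  expect_setequal(f$fixed$term,
                  c("(Intercept)", "speed", "sym_cws", "speed:sym_cws"))
  expect_true(all(f$fixed$se > 0))
  expect_true(all(f$fixed$p > 0 & f$fixed$p <= 1))
  expect_true(all(f$ranef_sd$sd >= 0))
  expect_false(f$fixed$reported[f$fixed$term == "sym_cws"])
  expect_equal(f$n_participants, length(unique(obs_stroke$participant_id)))
})

test_that("degrees-of-freedom method changes df and p but not estimates", {
  fs <- fit_symmetry_model(obs_stroke, "impulse", "stroke",
                           df_method = "satterthwaite")
  fk <- fit_symmetry_model(obs_stroke, "impulse", "stroke",
                           df_method = "kenward-roger")
  expect_equal(fs$fixed$estimate, fk$fixed$estimate, tolerance = 1e-8)
  expect_equal(fs$fixed$se, fk$fixed$se, tolerance = 0.2)  # KR adjusts SEs
})

test_that("estimates are invariant to row order", {
  set.seed(7)
  shuffled <- obs_stroke[sample.int(nrow(obs_stroke)), ]
  f1 <- fit_leg_model(obs_stroke, "impulse", df_method = "none")
  f2 <- fit_leg_model(shuffled, "impulse", df_method = "none")
  expect_equal(f1$fixed$estimate, f2$fixed$estimate, tolerance = 1e-6)
})

test_that("degenerate inputs are rejected", {
  one <- obs_stroke[obs_stroke$participant_id == obs_stroke$participant_id[1], ]
  expect_error(fit_symmetry_model(one, "peak", "stroke"),
               class = "propulsr_parameter_error")
  no_paretic <- obs_stroke[obs_stroke$leg != "paretic", ]
  expect_error(fit_leg_model(no_paretic, "peak"),
               class = "propulsr_parameter_error")
  expect_error(fit_per_leg_posthoc(obs_control, "peak", "paretic"),
               class = "propulsr_parameter_error")
})

test_that("the control symmetry intercept sits within 2 SE of one half", {
  f <- fit_symmetry_model(obs_control, "peak", "control",
                          df_method = "satterthwaite")
  ic <- f$fixed[f$fixed$term == "(Intercept)", ]
  expect_lt(abs(ic$estimate - 0.5), 2 * ic$se)
})

test_that("a zero-speed-effect cohort yields confidence intervals covering zero", {
  p <- default_params()
  p$control$peak$slope <- 0
  # keep the propulsion level well above the truncation floor so the null
  # scenario stays linear-Gaussian
  p$control$peak$intercept <- 1.0
  covered <- 0
  nrep <- 25
  for (r in seq_len(nrep)) {
    ds <- generate_cohort(p, "control", seed = 600 + r, mode = "metrics")
    obs <- process_dataset(ds)$observations
    f <- fit_control_metric_model(obs, "peak", df_method = "none")
    sl <- f$fixed[f$fixed$term == "speed", ]
    if (abs(sl$estimate) < 1.96 * sl$se) covered <- covered + 1
  }
  expect_gte(covered / nrep, 0.85)
})

test_that("identically generated legs yield null leg and interaction effects", {
  p <- default_params()
  p$stroke$peak$leg_effect <- 0
  p$stroke$peak$interaction <- 0
  p$stroke$peak$sd_leg <- 0
  p$stroke$peak$sd_interaction <- 0
  hits_leg <- 0; hits_int <- 0; nrep <- 10
  for (r in seq_len(nrep)) {
    ds <- generate_cohort(p, "stroke", seed = 700 + r, mode = "metrics")
    obs <- process_dataset(ds)$observations
    f <- suppressWarnings(fit_leg_model(obs, "peak", df_method = "none"))
    leg <- f$fixed[f$fixed$term == "leg_paretic", ]
    int <- f$fixed[f$fixed$term == "speed:leg_paretic", ]
    if (abs(leg$estimate) < 2 * leg$se) hits_leg <- hits_leg + 1
    if (abs(int$estimate) < 2 * int$se) hits_int <- hits_int + 1
  }
  expect_gte(hits_leg, 8)
  expect_gte(hits_int, 8)
})

test_that("diagnostics carry residual material of the right shape", {
  f <- fit_control_metric_model(obs_control, "impulse",
                                df_method = "satterthwaite")
  d <- compute_diagnostics(f)
  expect_length(d$residuals, f$n_obs)
  expect_length(d$fitted, f$n_obs)
  expect_equal(nrow(d$qq), f$n_obs)
  expect_lt(abs(mean(d$residuals)), sd(d$residuals))
  expect_true(is.finite(d$shapiro_p))
})

test_that("residuals of Gaussian-generated fits pass normality checks in most replicates", {
  p <- default_params()
  pass <- 0; nrep <- 10
  for (r in seq_len(nrep)) {
    ds <- generate_cohort(p, "control", seed = 800 + r, mode = "metrics")
    obs <- process_dataset(ds)$observations
    f <- fit_control_metric_model(obs, "impulse", df_method = "none")
    if (compute_diagnostics(f)$shapiro_p > 0.05) pass <- pass + 1
  }
  expect_gte(pass, 7)
})
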