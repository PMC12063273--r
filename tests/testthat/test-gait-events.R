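# One-participant waveform fixture with a short fixed schedule, shared
# across tests in this file.
make_wave_fixture <- function(seed = 71, crossover_rate = 0.1) {
  p <- default_params()
  p$stroke$n_participants <- 1
  p$stroke$cws_min <- 0.7; p$stroke$cws_max <- 0.7
  p$stroke$max_speed_margin <- 0
  p$crossover_rate <- crossover_rate
  generate_cohort(p, "stroke", seed = seed, mode = "waveforms")
}

ds_wave <- make_wave_fixture()

test_that("detected events match the generator's injected times within 20 ms", {
  sched <- ds_wave$schedules[[1]]
  j <- nrow(sched)  # fastest condition
  rc <- ds_wave$recordings[[sched$condition_id[j]]]
  mk <- rc$markers
  mk$ap <- lapply(mk$ap, filter_zero_phase, fs = mk$fs_marker)
  phases <- detect_stance_phases(mk, belt_speed = sched$speed[j])
  for (lg in c("left", "right")) {
    ev <- rc$events[rc$events$leg == lg, ]
    det <- phases[phases$leg == lg, ]
    # every truth IC inside the detected range has a detection within 2 samples
    ic_det <- det$ic_index
    for (t_ic in ev$ic_s) {
      i_true <- t_ic * 100 + 1
      if (i_true < min(ic_det) - 2 || i_true > max(ic_det) + 2) next
      expect_lte(min(abs(ic_det - i_true)), 2)
    }
    tc_det <- det$tc_index
    for (t_tc in ev$tc_s) {
      i_true <- t_tc * 100 + 1
      if (i_true < min(tc_det) - 2 || i_true > max(tc_det) + 2) next
      expect_lte(min(abs(tc_det - i_true)), 2)
    }
  }
})

test_that("detected cadence matches the generator cadence within 2 percent", {
  sched <- ds_wave$schedules[[1]]
  j <- 1
  rc <- ds_wave$recordings[[sched$condition_id[j]]]
  phases <- detect_stance_phases(rc$markers, belt_speed = sched$speed[j])
  for (lg in c("left", "right")) {
    ics <- phases$ic_index[phases$leg == lg]
    stride_s <- mean(diff(ics)) / 100
    cad_detected <- 120 / stride_s
    cad_true <- 60 + 40 * sched$speed[j]
    expect_lt(abs(cad_detected - cad_true) / cad_true, 0.02)
  }
  n_l <- sum(phases$leg == "left"); n_r <- sum(phases$leg == "right")
  expect_lte(abs(n_l - n_r), 1)
})

test_that("degenerate marker input raises a detection error; a single moving leg does not", {
  n <- 2000
  flat <- marker_set(
    ap = setNames(rep(list(rep(0.1, n)), 5), marker_labels()),
    ml = setNames(rep(list(rep(0, n)), 5), marker_labels()),
    fs_marker = 100)
  expect_error(detect_stance_phases(flat, belt_speed = 0.8),
               class = "propulsr_detection_error")

  t <- (0:(n - 1)) / 100
  move <- 0.2 * cos(2 * pi * t / 1.2)
  one_leg <- marker_set(
    ap = list(heel_left = move, toe_left = move + 0.25,
              heel_right = rep(0.1, n), toe_right = rep(0.35, n),
              pelvis = rep(0, n)),
    ml = setNames(rep(list(rep(0, n)), 5), marker_labels()),
    fs_marker = 100)
  ph <- detect_stance_phases(one_leg, belt_speed = 0.8)
  expect_gt(sum(ph$leg == "left"), 5)
  expect_equal(sum(ph$leg == "right"), 0)
})

test_that("event detection is invariant to a common AP translation", {
  sched <- ds_wave$schedules[[1]]
  rc <- ds_wave$recordings[[sched$condition_id[1]]]
  mk2 <- rc$markers
  mk2$ap <- lapply(mk2$ap, function(v) v + 3.21)
  p1 <- detect_stance_phases(rc$markers, belt_speed = sched$speed[1])
  p2 <- detect_stance_phases(mk2, belt_speed = sched$speed[1])
  expect_identical(p1, p2)
})

test_that("injected crossover steps are flagged, and only those", {
  sched <- ds_wave$schedules[[1]]
  for (j in seq_len(nrow(sched))) {
    cid <- sched$condition_id[j]
    rc <- ds_wave$recordings[[cid]]
    phases <- detect_stance_phases(rc$markers, belt_speed = sched$speed[j])
    phases <- flag_crossover_steps(phases, rc$markers)
    flagged <- phases[phases$exclusion_reason == "crossover", ]
    inj <- rc$events[rc$events$crossover, ]
    expect_equal(nrow(flagged), nrow(inj))
    if (nrow(inj)) {
      # flagged stances coincide with injected ones (match by IC time)
      for (k in seq_len(nrow(inj))) {
        i_true <- inj$ic_s[k] * 100 + 1
        expect_lte(min(abs(flagged$ic_index[flagged$leg == inj$leg[k]] - i_true)), 2)
      }
    }
  }
})

test_that("well-separated feet yield no crossover flags; the midline boundary counts", {
  phases <- data.frame(leg = "left", ic_index = 10L, tc_index = 60L,
                       valid = TRUE, exclusion_reason = "none",
                       stringsAsFactors = FALSE)
  n <- 100
  mk <- function(right_ml) marker_set(
    ap = setNames(rep(list(rep(0, n)), 5), marker_labels()),
    ml = list(heel_left = rep(-0.1, n), toe_left = rep(-0.1, n),
              heel_right = right_ml, toe_right = right_ml,
              pelvis = rep(0, n)),
    fs_marker = 100)
  clean <- flag_crossover_steps(phases, mk(rep(0.1, n)))
  expect_true(all(clean$valid))
  on_line <- rep(0.1, n); on_line[30] <- 0  # exactly on the midline once
  flagged <- flag_crossover_steps(phases, mk(on_line))
  expect_false(flagged$valid[1])
  expect_equal(flagged$exclusion_reason[1], "crossover")
})

test_that("valid-step counting tallies per leg", {
  ph <- data.frame(leg = rep(c("left", "right"), c(40, 38)),
                   valid = TRUE, stringsAsFactors = FALSE)
  ph$valid[1:3] <- FALSE
  counts <- count_valid_steps(ph)
  expect_equal(unname(counts[["left"]]), 37)
  expect_equal(unname(counts[["right"]]), 38)
  expect_length(count_valid_steps(ph[0, ]), 0)
})
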