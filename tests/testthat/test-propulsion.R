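test_that("the propulsion peak is the late-stance positive maximum", {
  seg <- half_sine_segment(120, 0.2, 100)
  pk <- find_propulsion_peak(seg$x)
  expect_true(pk$valid)
  expect_equal(pk$peak_value, 120, tolerance = 1e-3)
  expect_lte(abs(pk$peak_index - seg$peak_index), 1)

  expect_false(find_propulsion_peak(-abs(rnorm(50)) - 0.1)$valid)

  # two-lobe stance shape: braking minimum first, propulsion maximum later
  curve <- render_stance_curve(peak_n = 120, impulse_ns = 15, stance_s = 0.8,
                               fs = 100)
  pk2 <- find_propulsion_peak(curve)
  expect_gt(pk2$peak_index, which.min(curve))
  expect_equal(pk2$peak_value, max(curve))
})

test_that("ties between equal maxima resolve to the latest index", {
  x <- c(-1, 0.5, 2, 0.5, 2, 0.5, -1)
  pk <- find_propulsion_peak(x)
  expect_equal(pk$peak_index, 5L)
})

test_that("a clean positive lobe delimits to its own support", {
  seg <- half_sine_segment(100, 0.2, 100)
  pk <- find_propulsion_peak(seg$x)
  win <- delimit_propulsion_window(seg$x, pk$peak_index)
  expect_equal(win$bridged_dips, 0L)
  expect_true(all(seg$x[win$start_index:(win$end_index - 1)] > 0))
  expect_true(win$start_index == 1 || seg$x[win$start_index - 1] <= 0)
  expect_true(win$end_index > length(seg$x) || seg$x[win$end_index] <= 0)
})

test_that("an interior dip is bridged and subtracts; a trailing lobe is excluded", {
  fs <- 100
  curve_dip <- render_stance_curve(120, 15, 0.9, fs,
                                   interior_dip = list(depth_n = 10, duration_s = 0.06))
  pk <- find_propulsion_peak(curve_dip)
  win <- delimit_propulsion_window(curve_dip, pk$peak_index)
  expect_equal(win$bridged_dips, 1L)
  imp_dip <- compute_impulse(curve_dip, win, fs)

  curve_plain <- render_stance_curve(120, 15, 0.9, fs)
  pkp <- find_propulsion_peak(curve_plain)
  winp <- delimit_propulsion_window(curve_plain, pkp$peak_index)
  imp_plain <- compute_impulse(curve_plain, winp, fs)
  expect_lt(imp_dip, imp_plain)

  # signed additivity on a constructed lobe-dip-lobe sequence: the impulse
  # is the two positive areas minus the dip area of 1.0 N.s
  lobe1 <- half_sine_segment(100, 0.2, fs, pad_s = 0)$x
  dip <- -half_sine_segment(20, pi / 40, fs, pad_s = 0)$x  # area 1.0
  lobe2 <- half_sine_segment(50, 0.1, fs, pad_s = 0)$x
  x3 <- c(rep(0, 10), lobe1, dip[-1], lobe2[-1], rep(0, 10))
  pk3 <- find_propulsion_peak(x3)
  win3 <- delimit_propulsion_window(x3, pk3$peak_index)
  expect_equal(win3$bridged_dips, 1L)
  expected <- 2 * 100 * 0.2 / pi + 2 * 50 * 0.1 / pi - 1.0
  expect_equal(compute_impulse(x3, win3, fs), expected,
               tolerance = 0.01 * expected)

  curve_tr <- render_stance_curve(120, 15, 0.9, fs,
                                  trailing_lobe = list(amplitude_n = 20, duration_s = 0.05))
  pkt <- find_propulsion_peak(curve_tr)
  wint <- delimit_propulsion_window(curve_tr, pkt$peak_index)
  expect_equal(wint$bridged_dips, 0L)
  imp_tr <- compute_impulse(curve_tr, wint, fs)
  expect_equal(imp_tr, imp_plain, tolerance = 0.01 * abs(imp_plain))
})

test_that("the trapezoid impulse matches the closed-form half-sine area", {
  seg <- half_sine_segment(100, 0.2, 100)
  pk <- find_propulsion_peak(seg$x)
  win <- delimit_propulsion_window(seg$x, pk$peak_index)
  imp <- compute_impulse(seg$x, win, 100)
  expect_equal(imp, 12.732, tolerance = 0.005 * 12.732)
  expect_equal(imp, seg$area, tolerance = 0.005 * seg$area)
  # and across a range of lobe shapes
  for (A in c(40, 150)) for (T in c(0.12, 0.3)) {
    s <- half_sine_segment(A, T, 100)
    w <- delimit_propulsion_window(s$x, find_propulsion_peak(s$x)$peak_index)
    expect_equal(compute_impulse(s$x, w, 100), s$area, tolerance = 0.005 * s$area)
  }
})

test_that("mass normalization is division by mass with guarded input", {
  expect_equal(normalize_by_mass(120, 80), 1.5)
  expect_equal(normalize_by_mass(12.732, 80), 12.732 / 80)
  expect_equal(normalize_by_mass(0, 80), 0)
  expect_error(normalize_by_mass(120, 0), class = "propulsr_parameter_error")
  expect_error(normalize_by_mass(120, -5), class = "propulsr_parameter_error")
})

test_that("scaling a stance curve scales peak and impulse, window unchanged", {
  curve <- render_stance_curve(120, 15, 0.9, 100)
  for (c_scale in c(0.5, 3)) {
    a <- find_propulsion_peak(curve); b <- find_propulsion_peak(curve * c_scale)
    expect_equal(b$peak_value, c_scale * a$peak_value)
    wa <- delimit_propulsion_window(curve, a$peak_index)
    wb <- delimit_propulsion_window(curve * c_scale, b$peak_index)
    expect_equal(wa[c("start_index", "end_index")], wb[c("start_index", "end_index")])
    expect_equal(compute_impulse(curve * c_scale, wb, 100),
                 c_scale * compute_impulse(curve, wa, 100))
  }
})

test_that("condition summaries enforce the 23-step rule at its boundary", {
  ok <- summarize_condition(fake_steps(30, 30), speed = 0.8, condition_id = "c")
  expect_true(attr(ok, "included"))
  expect_equal(ok$peak, c(1.5, 1.5))

  low <- summarize_condition(fake_steps(22, 30), speed = 0.8, condition_id = "c")
  expect_false(attr(low, "included"))
  expect_equal(attr(low, "exclusion_reason"), "too_few_steps")

  edge <- summarize_condition(fake_steps(23, 23), speed = 0.8, condition_id = "c")
  expect_true(attr(edge, "included"))

  # invalid steps do not count toward the threshold
  inv <- summarize_condition(fake_steps(30, 30, n_invalid_left = 8),
                             speed = 0.8, condition_id = "c")
  expect_false(attr(inv, "included"))
  expect_equal(inv$n_steps[inv$leg == "left"], 22)
})

test_that("the condition mean is invariant to step order", {
  set.seed(9)
  st <- fake_steps(40, 40)
  st$peak <- rnorm(80, 1.5, 0.2); st$impulse <- rnorm(80, 0.25, 0.03)
  a <- summarize_condition(st, 0.8, "c")
  b <- summarize_condition(st[sample.int(80), ], 0.8, "c")
  expect_equal(a$peak, b$peak)
  expect_equal(a$impulse, b$impulse)
})

test_that("participants are excluded only at two or more failing conditions", {
  mk_cond <- function(id, fail) {
    s <- summarize_condition(fake_steps(if (fail) 20 else 30, 30),
                             speed = 0.8, condition_id = id)
    s
  }
  one_fail <- lapply(1:8, function(i) mk_cond(paste0("c", i), i == 3))
  d1 <- apply_participant_exclusion(one_fail)
  expect_true(d1$include_participant)
  expect_equal(length(unique(d1$kept$condition_id)), 7)

  two_fail <- lapply(1:8, function(i) mk_cond(paste0("c", i), i %in% c(3, 6)))
  d2 <- apply_participant_exclusion(two_fail)
  expect_false(d2$include_participant)
  expect_null(d2$kept)

  no_fail <- lapply(1:8, function(i) mk_cond(paste0("c", i), FALSE))
  d3 <- apply_participant_exclusion(no_fail)
  expect_true(d3$include_participant)
  expect_equal(length(unique(d3$kept$condition_id)), 8)
})
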