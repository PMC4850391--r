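test_that("target counts follow the design distribution", {
  expect_identical(draw_target_count(c(`2` = 1), 10), rep(2L, 10))
  expect_error(draw_target_count(c(`2` = 0.7, `3` = 0.7)), "probability")

  set.seed(21)
  k <- draw_target_count(n = 1e5)
  f2 <- mean(k == 2)
  f3 <- mean(k == 3)
  f4 <- mean(k == 4)
  expect_lt(abs(f2 - 0.5), 3 * sqrt(0.5 * 0.5 / 1e5))
  expect_lt(abs(f3 - 0.375), 3 * sqrt(0.375 * 0.625 / 1e5))
  expect_lt(abs(f4 - 0.125), 3 * sqrt(0.125 * 0.875 / 1e5))
  # chi-square goodness of fit not rejected at alpha = 0.01
  gof <- chisq.test(tabulate(k, 4)[2:4], p = c(0.5, 0.375, 0.125))
  expect_gt(gof$p.value, 0.01)
})

test_that("target schedules respect margins and minimum gaps", {
  cfg <- experiment_config()
  set.seed(22)
  for (r in 1:200) {
    n <- sample(2:4, 1)
    s <- draw_target_schedule(n, cfg)
    expect_true(all(s >= 0.8 - 1e-12))
    expect_true(all(s <= 6.25 - 0.8 + 1e-12))
    if (n > 1) expect_true(all(diff(s) >= 0.8 - 1e-12))
  }
  # singleton feasible set: only one legal onset
  cfg1 <- experiment_config(trial_duration = 1.6, edge_margin = 0.8,
                            target_count_probs = c(`1` = 1))
  expect_equal(draw_target_schedule(1, cfg1), 0.8)
  # infeasible request
  expect_error(draw_target_schedule(7, cfg), "cannot schedule")
})

test_that("detection probability has the declared psychometric structure", {
  pos <- positions_exp2()
  ob0 <- observer_model(pos, guess_rate = 0, lapse_rate = 0,
                        modulation_depth = 0)
  expect_equal(detection_probability(ob0, "I", 100, 0.3), 0.5)
  # cosine extremes under modulation
  obm <- observer_model(pos, guess_rate = 0, lapse_rate = 0,
                        modulation_depth = 0.4)
  pref <- obm$preferred_phase_per_position[["I"]]
  p_peak <- detection_probability(obm, "I", 100, pref)
  p_trough <- detection_probability(obm, "I", 100, pref + pi)
  expect_gt(p_peak, p_trough)
  expect_equal(p_peak - p_trough, 0.5 * 0.4) # m * baseline at threshold
  # no modulation -> flat in phase
  phis <- seq(-pi, pi, length.out = 17)
  expect_equal(detection_probability(ob0, "III", 80, phis),
               rep(detection_probability(ob0, "III", 80, 0), 17))
  expect_error(detection_probability(ob0, "XX", 100, 0), "unknown position")
})

test_that("staircase rule and its equilibrium behave as designed", {
  expect_equal(staircase_update(100, "hit", 1.1), 100 / 1.1)
  expect_equal(staircase_update(100, "miss", 1.1), 110)
  expect_equal(staircase_update(250, "miss", 1.1), 255) # ceiling
  expect_error(staircase_update(0, "hit"), "current_luminance")

  set.seed(23)
  tr <- simulate_staircase(observer_model(), "I", n_targets = 500)
  rate <- mean(tr$detected[251:500])
  expect_lt(abs(rate - 0.5), 0.05)
  # staircase keeps luminance near the 50% point of the psychometric curve
  expect_lt(abs(median(tr$luminance[251:500]) - 100), 25)
})

test_that("simulated experiments satisfy every scheduling invariant", {
  cfg <- experiment_config()
  ds <- simulate_experiment(cfg, observer_exp2(), n_subjects = 1,
                            targets_per_cell = 33, seed = 24)[[1]]
  tg <- ds$targets
  # ~33 targets per (bin, position) cell: 8 x 5 cells
  expect_gte(nrow(tg), 1320)
  expect_lt(nrow(tg), 1330)
  expect_true(all(tg$onset_s >= 0.8 - 1e-12))
  expect_true(all(tg$onset_s <= 6.25 - 0.8 + 1e-12))
  for (tr in split(tg$onset_s, tg$trial)) {
    if (length(tr) > 1) expect_true(all(diff(sort(tr)) >= 0.8 - 1e-12))
  }
  expect_identical(assign_phase_bin(tg$phase_rad, cfg$binning), tg$bin)
  # per-cell counts hover around the design value
  cells <- table(tg$bin, tg$position_id)
  expect_gt(min(cells), 10)
  expect_equal(mean(cells), nrow(tg) / 40)
})

test_that("a fixed seed reproduces the dataset bit for bit", {
  cfg <- experiment_config()
  a <- simulate_experiment(cfg, observer_exp2(), n_subjects = 2,
                           targets_per_cell = 5, seed = 25)
  b <- simulate_experiment(cfg, observer_exp2(), n_subjects = 2,
                           targets_per_cell = 5, seed = 25)
  expect_identical(a, b)
})

test_that("the null generator pools to the staircase equilibrium rate", {
  cfg <- experiment_config()
  ds <- simulate_experiment(cfg, observer_model(modulation_depth = 0),
                            n_subjects = 1, targets_per_cell = 33,
                            seed = 26)[[1]]
  n <- nrow(ds$targets)
  expect_lt(abs(mean(ds$targets$detected) - 0.5), 3 * sqrt(0.25 / n) + 0.02)
})
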