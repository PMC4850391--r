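test_that("binning conserves targets and computes per-bin hit rates", {
  cfg <- experiment_config()
  ds <- simulate_experiment(cfg, observer_exp2(), n_subjects = 1,
                            targets_per_cell = 20, seed = 31)[[1]]
  for (pid in c("I", "III")) {
    b <- bin_performance(ds, pid, cfg$binning)
    tg <- ds$targets[ds$targets$position_id == pid, ]
    expect_equal(sum(b$n_targets), nrow(tg))
    expect_equal(sum(b$n_hits), sum(tg$detected))
    ok <- b$n_targets > 0
    expect_equal(b$hit_rate[ok], b$n_hits[ok] / b$n_targets[ok])
  }
  expect_error(bin_performance(ds, "nowhere"), "no targets")
})

test_that("ceiling data fit flat with zero amplitude", {
  b <- make_binned(rep(1, 8))
  f <- fit_cosine(b)
  expect_equal(f$baseline, 1)
  expect_equal(f$half_amplitude, 0)
  expect_true(f$degenerate)
  expect_identical(f$preferred_phase, 0) # flat-input convention
})

test_that("noiseless cosine inputs are recovered exactly", {
  h <- 0.5 + 0.11 * cos(centers8 - pi / 4)
  f <- fit_cosine(make_binned(h))
  expect_equal(f$baseline, 0.5, tolerance = 1e-12)
  expect_equal(f$half_amplitude, 0.11, tolerance = 1e-12)
  expect_equal(f$preferred_phase, pi / 4, tolerance = 1e-12)
  expect_equal(f$peak_to_trough, 0.22, tolerance = 1e-12)

  set.seed(32)
  for (r in 1:50) {
    base <- runif(1, 0.2, 0.8)
    amp <- runif(1, 0, min(base, 1 - base))
    ph <- runif(1, -pi, pi)
    f <- fit_cosine(make_binned(base + amp * cos(centers8 - ph)))
    expect_equal(f$baseline, base, tolerance = 1e-10)
    expect_equal(f$half_amplitude, amp, tolerance = 1e-10)
    if (amp > 1e-6) expect_lt(circ_dist(f$preferred_phase, ph), 1e-8)
  }
})

test_that("closed-form fit agrees with brute-force least squares", {
  set.seed(33)
  for (r in 1:100) {
    h <- runif(8)
    f <- fit_cosine(make_binned(h))
    bf <- brute_force_cosfit(h)
    expect_equal(f$baseline, bf$baseline, tolerance = 1e-9)
    expect_equal(f$half_amplitude, bf$half_amplitude, tolerance = 1e-5)
    if (f$half_amplitude > 1e-3) {
      expect_lt(circ_dist(f$preferred_phase, bf$preferred_phase), 1.1e-3)
    }
  }
})

test_that("empty bins are excluded when enough usable bins remain", {
  h <- 0.5 + 0.1 * cos(centers8 - 1)
  n <- rep(50, 8); n[3] <- 0
  b <- binned_performance("P", centers8, n, round(h * n),
                          hit_rate = replace(h, 3, NA))
  expect_warning(f <- fit_cosine(b), "empty bin")
  expect_equal(f$half_amplitude, 0.1, tolerance = 1e-9)
  expect_equal(f$n_bins_used, 7)
  # too few usable bins for 3 parameters
  n2 <- c(50, 50, rep(0, 6))
  b2 <- binned_performance("P", centers8, n2, round(h * n2))
  expect_warning(expect_error(fit_cosine(b2), "usable bins"), "empty")
})

test_that("two bins identify amplitude as half the rate difference", {
  b <- binned_performance("P", phase_binning(2)$bin_centers,
                          c(50, 50), c(20, 30))
  f <- fit_cosine(b)
  expect_equal(f$half_amplitude, abs(0.6 - 0.4) / 2)
  expect_equal(f$peak_to_trough, 0.2)
  expect_true(abs(sin(f$preferred_phase)) < 1e-12) # phase forced to {0, pi}
})

test_that("group averaging is the unweighted mean with summed counts", {
  b1 <- make_binned(rep(0.4, 8), n = 40)
  b2 <- make_binned(rep(0.6, 8), n = 60)
  g <- group_average_bins(list(b1, b2))
  expect_equal(g$hit_rate, rep(0.5, 8))
  expect_equal(g$n_targets, rep(100, 8))
  # order invariance
  g2 <- group_average_bins(list(b2, b1))
  expect_equal(g$hit_rate, g2$hit_rate)
  # identical subjects: group fit equals the individual fit
  h <- 0.5 + 0.12 * cos(centers8 + 0.8)
  gi <- group_average_bins(list(make_binned(h), make_binned(h)))
  expect_equal(fit_cosine(gi)$half_amplitude,
               fit_cosine(make_binned(h))$half_amplitude)
  expect_equal(fit_cosine(gi)$preferred_phase,
               fit_cosine(make_binned(h))$preferred_phase)
  # binning mismatch rejected
  bb <- make_binned(rep(0.5, 4), centers = phase_binning(4)$bin_centers)
  expect_error(group_average_bins(list(b1, bb)), "different phase binnings")
})

test_that("modulation depth is twice the half-amplitude, baseline-invariant", {
  h <- 0.5 + 0.11 * cos(centers8 - pi / 4)
  expect_equal(modulation_depth(fit_cosine(make_binned(h))), 0.22)
  expect_equal(modulation_depth(fit_cosine(make_binned(h + 0.2))), 0.22,
               tolerance = 1e-10)
  expect_equal(modulation_depth(fit_cosine(make_binned(rep(0.5, 8)))), 0)
})
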