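test_that("SOA-independent performance yields no oscillation at any position", {
  set.seed(61)
  soa_df <- simulate_soa_dataset(n_subjects = 5, targets_per_soa = 33,
                                 rate = 0.5)
  res <- analyze_soa_control(soa_df, n_surrogates = 1000, seed = 611)
  expect_equal(nrow(res$summary), 5)
  expect_false(any(res$summary$significant))
  # counts conserved through the +/-50 ms merge: 9 SOA cells -> 8 phase bins
  grp <- res$per_position[[1]]$binned
  expect_equal(sum(grp$n_targets), 5 * 9 * 33)
  expect_equal(length(grp$bin_centers), 8)
  expect_equal(grp$n_targets[abs(grp$bin_centers + pi) < 1e-6], 2 * 5 * 33)
})

test_that("cosine-in-SOA performance is recovered with its injected phase", {
  set.seed(62)
  inj_phase <- -pi / 3
  gen <- function(phi) 0.5 + 0.15 * cos(phi - inj_phase)
  soa_df <- simulate_soa_dataset(n_subjects = 8, targets_per_soa = 60,
                                 rate = gen)
  res <- analyze_soa_control(soa_df, n_surrogates = 1000, seed = 621)
  expect_true(all(res$summary$significant))
  for (pp in res$per_position) {
    expect_lt(circ_dist(pp$fit$preferred_phase, inj_phase), pi / 8)
  }
})

test_that("incomplete SOA grids are rejected", {
  soa_df <- simulate_soa_dataset(n_subjects = 2)
  expect_error(analyze_soa_control(soa_df[soa_df$soa_ms != 25, ]),
               "missing or duplicated")
})

test_that("luminance rearrangement reproduces the fixed level-to-bin map", {
  # distinct rates per level so the emitted order is fully identifiable
  lum <- data.frame(subject = "S01", level = c(64, 128, 192, 255),
                    n = 100, hits = c(30, 45, 60, 80))
  res <- rearrange_luminance_to_bins(lum, n_surrogates = 200, seed = 63)
  expect_equal(res$binned$bin_centers,
               c(-pi, -3 * pi / 4, -pi / 2, -pi / 4, 0, pi / 4, pi / 2,
                 3 * pi / 4))
  expect_equal(res$binned$hit_rate,
               c(0.80, 0.60, 0.45, 0.30, 0.30, 0.30, 0.45, 0.60))
  expect_equal(res$binned$n_targets, rep(100, 8))
})

test_that("emulated luminance curves always fit with phase 0 or pi", {
  set.seed(64)
  for (r in 1:200) {
    lum <- data.frame(subject = "S01", level = c(64, 128, 192, 255),
                      n = 50, hits = sample(0:50, 4, replace = TRUE))
    fit <- rearrange_luminance_to_bins(lum, n_surrogates = 1)$fit
    expect_lt(abs(sin(fit$preferred_phase)), 1e-8)
  }
  # constant performance across levels -> zero amplitude
  flat <- data.frame(subject = "S01", level = c(64, 128, 192, 255),
                     n = 50, hits = rep(25, 4))
  expect_equal(rearrange_luminance_to_bins(flat, n_surrogates = 1)$fit$peak_to_trough, 0)
})

test_that("luminance-driven detection is flagged only where it is injected", {
  set.seed(65)
  strong <- simulate_luminance_dataset(
    n_subjects = 6, positions = positions_exp2()[1, , drop = FALSE],
    targets_per_level = 60, rate = function(l) 0.30 + 0.4 * (l - 64) / 191)
  nullp <- simulate_luminance_dataset(
    n_subjects = 6, positions = positions_exp2()[5, , drop = FALSE],
    targets_per_level = 60, rate = 0.5)
  res <- analyze_luminance_control(rbind(strong, nullp),
                                   n_surrogates = 1000, seed = 651)
  expect_true(res$summary$significant[res$summary$position_id == "I"])
  expect_false(res$summary$significant[res$summary$position_id == "V"])
})

test_that("missing luminance levels are rejected", {
  lum <- data.frame(subject = "S01", level = c(64, 128, 192),
                    n = 50, hits = c(10, 20, 30))
  expect_error(rearrange_luminance_to_bins(lum), "level")
})
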