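# direct binomial null generator at the binned level: S subjects, common
# rate curve p(phi), n trials per bin
draw_null_binned <- function(n_subjects = 1, n_per_bin = 50, p = 0.5) {
  pk <- if (is.function(p)) p(centers8) else rep(p, 8)
  lapply(seq_len(n_subjects), function(s) {
    hits <- rbinom(8, n_per_bin, pk)
    behavosc::binned_performance("P", centers8, rep(n_per_bin, 8), hits)
  })
}

test_that("identical outcomes in every bin saturate the amplitude test", {
  b <- make_binned(rep(1, 8), n = 20) # every target detected
  mc <- mc_amplitude_test(list(b), n_surrogates = 500, seed = 41)
  expect_equal(mc$observed_statistic, 0)
  expect_equal(mc$p_raw, 1) # surrogates are all-hit too: counts preserved
  expect_equal(mc$p_conservative, 1)
})

test_that("amplitude test is reproducible under a fixed seed", {
  set.seed(42)
  binned <- draw_null_binned(n_subjects = 3)
  a <- mc_amplitude_test(binned, n_surrogates = 800, seed = 7)
  b <- mc_amplitude_test(binned, n_surrogates = 800, seed = 7)
  expect_identical(a$p_raw, b$p_raw)
  expect_identical(a$surrogate_quantiles, b$surrogate_quantiles)
})

test_that("null p-values are uniform under the equal-performance null", {
  set.seed(43)
  ps <- replicate(400, {
    mc_amplitude_test(draw_null_binned(n_subjects = 2), n_surrogates = 500)$p_raw
  })
  # Kolmogorov-Smirnov against uniform at alpha = 0.01 (critical value
  # 1.628 / sqrt(n) for n = 400)
  d <- max(abs(sort(ps) - (seq_along(ps) - 0.5) / length(ps)))
  expect_lt(d, 1.628 / sqrt(400))
  expect_lt(abs(mean(ps <= 0.05) - 0.05), 0.04)
})

test_that("stronger injected modulation never raises the median p-value", {
  set.seed(44)
  depths <- c(0, 0.1, 0.2, 0.3)
  med <- vapply(depths, function(m) {
    ps <- replicate(50, {
      gen <- function(phi) 0.5 + (m / 2) * cos(phi - 1)
      mc_amplitude_test(draw_null_binned(2, 50, gen), n_surrogates = 400)$p_raw
    })
    median(ps)
  }, 1)
  expect_true(all(diff(med) <= 0))
})

test_that("phase-difference test saturates for identical curves and rejects flat ones", {
  h <- 0.5 + 0.15 * cos(centers8 - 0.5)
  a <- make_binned(h, n = 400, position_id = "A")
  b <- make_binned(h, n = 400, position_id = "B")
  mc <- mc_phase_difference_test(a, b, n_surrogates = 500, seed = 45)
  expect_equal(mc$observed_statistic, 0)
  expect_equal(mc$p_raw, 1)
  flat <- make_binned(rep(0.5, 8), n = 400)
  expect_error(mc_phase_difference_test(a, flat, n_surrogates = 100),
               "degenerate")
})

test_that("phase-difference test is seed-reproducible and detects offsets", {
  a <- make_binned(0.5 + 0.11 * cos(centers8), n = 400, position_id = "A")
  b <- make_binned(0.5 + 0.11 * cos(centers8 - pi / 2), n = 400,
                   position_id = "B")
  r1 <- mc_phase_difference_test(a, b, n_surrogates = 1000, seed = 46)
  r2 <- mc_phase_difference_test(a, b, n_surrogates = 1000, seed = 46)
  expect_identical(r1$p_raw, r2$p_raw)
  expect_equal(r1$observed_statistic, pi / 2, tolerance = 1e-9)
  expect_lt(r1$p_raw, 0.01)
})

test_that("Benjamini-Hochberg step-up flags match the closed-form thresholds", {
  r <- fdr_adjust(c(0.01, 0.02, 0.03, 0.04, 0.05), q = 0.05)
  expect_true(all(r$significant)) # i * q / m = 0.01 * i exactly
  expect_equal(r$p_adj, rep(0.05, 5))
  expect_false(any(fdr_adjust(rep(1, 6))$significant))
  one <- fdr_adjust(0.04, q = 0.05)
  expect_equal(one$p_adj, 0.04) # m = 1 leaves the value unchanged
  expect_true(one$significant)
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  # monotone flags: rejecting p implies rejecting all smaller p
  set.seed(47)
  for (r in 1:20) {
    p <- runif(10)
    fl <- fdr_adjust(p, q = 0.2)
    o <- order(p)
    expect_true(all(diff(as.integer(fl$significant[o])) <= 0))
  }
})
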