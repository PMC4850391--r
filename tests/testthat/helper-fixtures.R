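# shared fixtures: everything is generated in code at test time

centers8 <- behavosc::phase_binning(8)$bin_centers

# binned-performance object from rates (counts default to 100 per bin)
make_binned <- function(rates, n = 100, position_id = "P",
                        centers = centers8) {
  behavosc::binned_performance(position_id, centers,
                               n_targets = rep_len(n, length(centers)),
                               n_hits = round(rates * rep_len(n, length(centers))),
                               hit_rate = rates)
}

# independent least-squares oracle for the cosine fit: grid search over the
# preferred phase (step 1e-3 rad), closed-form baseline and non-negative
# amplitude at each grid phase, minimising the unweighted SSE
brute_force_cosfit <- function(h, centers = centers8, step = 1e-3) {
  grid <- seq(-pi, pi, by = step)
  hbar <- mean(h)
  best <- list(sse = Inf)
  C <- cos(outer(grid, centers, "-"))
  proj <- as.vector(C %*% (h - hbar))
  denom <- rowSums(C^2)
  a <- pmax(proj / denom, 0)
  sse <- vapply(seq_along(grid), function(i) {
    sum((h - hbar - a[i] * C[i, ])^2)
  }, 1)
  i <- which.min(sse)
  list(baseline = hbar, half_amplitude = a[i], preferred_phase = grid[i],
       sse = sse[i])
}

# single-position layout for calibration runs
layout_one <- function() {
  data.frame(id = "P1", eccentricity = 5.4, quadrant = "upper_left",
             is_adjacent_to_disc = TRUE, stringsAsFactors = FALSE)
}

# circular absolute distance in [0, pi]
circ_dist <- function(a, b) abs(behavosc::wrap_phase(a - b))
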