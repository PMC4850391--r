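#' Synthetic observer model
#'
#' A generative stand-in for a human observer whose detection probability is
#' modulated in cosine fashion by the phase of the entraining oscillation.
#' Detection of a target of luminance `L` at oscillation phase `phi` follows
#'
#' `p = guess + (1 - guess - lapse) * logistic(slope * (log L - log theta)) *
#'      (1 + (m / 2) * cos(phi - phi_pref))`
#'
#' clipped to `[0, 1]`, where `theta` is the position's 50%-detection
#' threshold, `m` the position's relative peak-to-trough modulation depth and
#' `phi_pref` its preferred phase. Positions adjacent to the oscillating disc
#' receive the "local" preferred phase, all others the common "global" phase,
#' reflecting the two entrainment components the analysis is designed to
#' separate. The modulation multiplies the psychometric term only, so `m` is
#' the peak-to-trough fraction of detection probability at threshold.
#'
#' @param positions Position layout data frame (see [positions_exp2()]).
#' @param threshold Luminance (0-255 scale) at 50% detection; scalar or one
#'   value per position.
#' @param slope Logistic steepness per unit log-luminance.
#' @param guess_rate Probability of a hit at zero stimulus strength.
#' @param lapse_rate Probability of missing regardless of strength.
#' @param modulation_depth Relative peak-to-trough modulation `m` in `[0, 1]`;
#'   scalar or one value per position.
#' @param local_phase Preferred phase (radians) at the position adjacent to
#'   the disc.
#' @param global_phase Preferred phase (radians) at all other positions.
#' @return An object of class `observer_model`.
#' @export
observer_model <- function(positions = positions_exp2(),
                           threshold = 100,
                           slope = 8,
                           guess_rate = 0,
                           lapse_rate = 0.02,
                           modulation_depth = 0,
                           local_phase = pi / 4,
                           global_phase = -pi / 4) {
  validate_positions(positions)
  n_pos <- nrow(positions)
  threshold <- rep_len(threshold, n_pos)
  modulation_depth <- rep_len(modulation_depth, n_pos)
  stopifnot(all(threshold > 0), all(threshold <= 255),
            slope > 0,
            guess_rate >= 0, lapse_rate >= 0,
            guess_rate + lapse_rate < 1,
            all(modulation_depth >= 0), all(modulation_depth <= 1))
  local_phase <- wrap_phase(local_phase)
  global_phase <- wrap_phase(global_phase)
  structure(
    list(
      positions = positions,
      threshold_per_position = stats::setNames(threshold, positions$id),
      slope = slope,
      guess_rate = guess_rate,
      lapse_rate = lapse_rate,
      modulation_depth_per_position = stats::setNames(modulation_depth, positions$id),
      local_phase = local_phase,
      global_phase = global_phase,
      preferred_phase_per_position = stats::setNames(
        ifelse(positions$is_adjacent_to_disc, local_phase, global_phase),
        positions$id
      )
    ),
    class = "observer_model"
  )
}

#' Observer profile matching the 5-position alpha-entrainment condition
#'
#' Convenience constructor with modulation depths that reproduce, at the 50%
#' staircase baseline, a mean absolute peak-to-trough modulation of ~22% with
#' an ~18% drop from the position nearest the disc to its neighbour, and a
#' quarter-cycle local/global phase separation.
#'
#' @param positions Position layout (defaults to the 5-position layout).
#' @param ... Passed on to [observer_model()].
#' @return An `observer_model`.
#' @export
observer_exp2 <- function(positions = positions_exp2(), ...) {
  observer_model(
    positions = positions,
    modulation_depth = rep_len(c(0.52, 0.45, 0.43, 0.40, 0.40), nrow(positions)),
    ...
  )
}

#' @export
print.observer_model <- function(x, ...) {
  cat("Synthetic observer\n")
  cat(sprintf("  slope %.3g, guess %.3g, lapse %.3g\n",
              x$slope, x$guess_rate, x$lapse_rate))
  cat(sprintf("  local phase %.3f rad, global phase %.3f rad\n",
              x$local_phase, x$global_phase))
  df <- data.frame(
    position = names(x$threshold_per_position),
    threshold = unname(x$threshold_per_position),
    modulation = unname(x$modulation_depth_per_position),
    preferred_phase = unname(x$preferred_phase_per_position)
  )
  print(df, row.names = FALSE)
  invisible(x)
}

#' Draw the number of targets in a trial
#'
#' @param probs Named probability vector over target counts (default the
#'   design distribution: 2 targets with probability 0.5, 3 with 0.375, 4
#'   with 0.125).
#' @param n Number of draws.
#' @return Integer vector of target counts.
#' @export
draw_target_count <- function(probs = c(`2` = 0.5, `3` = 0.375, `4` = 0.125),
                              n = 1L) {
  counts <- suppressWarnings(as.integer(names(probs)))
  if (anyNA(counts) || any(probs < 0) || abs(sum(probs) - 1) > 1e-9) {
    stop("`probs` must be a probability distribution named by integer counts",
         call. = FALSE)
  }
  if (length(counts) == 1L) return(rep(counts, n))
  sample(counts, size = n, replace = TRUE, prob = probs)
}

#' Draw target onset times for one trial
#'
#' Onsets avoid an `edge_margin` at both ends of the trial and keep at least
#' `min_gap` between consecutive targets. Sampling is uniform over the
#' feasible set via the ordered-gap construction: subtracting the mandatory
#' gaps maps the constrained ordered times onto plain order statistics of
#' uniforms on a shrunken interval.
#'
#' @param n Number of targets.
#' @param config An [experiment_config()].
#' @return Sorted numeric vector of `n` onset times in seconds.
#' @export
draw_target_schedule <- function(n, config = experiment_config()) {
  n <- as.integer(n)
  stopifnot(n >= 1L)
  a <- config$edge_margin
  b <- config$trial_duration - config$edge_margin
  g <- config$min_gap
  span <- b - a - (n - 1L) * g
  if (span < 0) {
    stop(sprintf(
      "cannot schedule %d targets: %d gaps of %.3g s exceed the %.3g s usable span",
      n, n - 1L, g, b - a), call. = FALSE)
  }
  u <- sort(stats::runif(n, min = a, max = a + span))
  u + (seq_len(n) - 1L) * g
}

#' Phase-modulated detection probability
#'
#' See [observer_model()] for the formula.
#'
#' @param observer An [observer_model()].
#' @param position_id Position identifier (single value).
#' @param luminance Target luminance on the 0-255 scale (vectorised).
#' @param phi Oscillation phase at target onset, radians (vectorised).
#' @return Detection probability in `[0, 1]`.
#' @export
detection_probability <- function(observer, position_id, luminance, phi) {
  stopifnot(inherits(observer, "observer_model"))
  position_id <- as.character(position_id)
  if (!position_id %in% names(observer$threshold_per_position)) {
    stop(sprintf("unknown position '%s'", position_id), call. = FALSE)
  }
  stopifnot(all(luminance > 0))
  theta <- observer$threshold_per_position[[position_id]]
  m <- observer$modulation_depth_per_position[[position_id]]
  phi_pref <- observer$preferred_phase_per_position[[position_id]]
  psych <- stats::plogis(observer$slope * (log(luminance) - log(theta)))
  gain <- 1 + (m / 2) * cos(phi - phi_pref)
  p <- observer$guess_rate +
    (1 - observer$guess_rate - observer$lapse_rate) * psych * gain
  pmin(pmax(p, 0), 1)
}

#' One step of the multiplicative 1-up/1-down staircase
#'
#' A hit divides the luminance by `step`, a miss multiplies it by `step`
#' (capped at 255). The equilibrium of this rule is the 50%-detection point,
#' matching the design goal of holding hit rate near 50%.
#'
#' @param current_luminance Current target luminance in `(0, 255]`.
#' @param outcome `"hit"` or `"miss"` (or logical: `TRUE` = hit).
#' @param step Multiplicative step factor, > 1.
#' @return Updated luminance.
#' @export
staircase_update <- function(current_luminance, outcome, step = 1.1) {
  stopifnot(current_luminance > 0, current_luminance <= 255, step > 1)
  if (is.logical(outcome)) outcome <- ifelse(outcome, "hit", "miss")
  outcome <- match.arg(outcome, c("hit", "miss"))
  if (outcome == "hit") {
    current_luminance / step
  } else {
    min(current_luminance * step, 255)
  }
}

#' Run a staircase against the synthetic observer
#'
#' Simulates a sequence of targets at one position, each detected with the
#' observer's phase-modulated probability at the staircase's current
#' luminance, updating the staircase after every target.
#'
#' @param observer An [observer_model()].
#' @param position_id Position at which targets appear.
#' @param n_targets Number of targets to simulate.
#' @param step Staircase step factor.
#' @param start_luminance Initial target luminance.
#' @param phases Oscillation phases at the target onsets; defaults to
#'   independent uniform draws on `[-pi, pi)`.
#' @return A data frame with one row per target: `luminance`, `phi`,
#'   `p_detect`, `detected`.
#' @export
simulate_staircase <- function(observer, position_id, n_targets = 500L,
                               step = 1.1, start_luminance = 150,
                               phases = NULL) {
  n_targets <- as.integer(n_targets)
  stopifnot(n_targets >= 1L)
  if (is.null(phases)) {
    phases <- stats::runif(n_targets, -pi, pi)
  }
  phases <- rep_len(phases, n_targets)
  lum <- numeric(n_targets)
  p <- numeric(n_targets)
  hit <- logical(n_targets)
  cur <- start_luminance
  for (i in seq_len(n_targets)) {
    lum[i] <- cur
    p[i] <- detection_probability(observer, position_id, cur, phases[i])
    hit[i] <- stats::runif(1) < p[i]
    cur <- staircase_update(cur, hit[i], step)
  }
  data.frame(luminance = lum, phi = phases, p_detect = p, detected = hit)
}

#' Simulate a full entrainment experiment
#'
#' Generates one dataset per subject: trials of `config$trial_duration`
#' seconds, each containing 2-4 targets drawn from the design distribution
#' and scheduled under the margin/gap rules; targets land at uniformly
#' sampled positions; the disc's oscillation phase at trial start is uniform,
#' so onset phases cover the cycle; a per-position 1-up/1-down staircase sets
#' target luminance; detection is Bernoulli with the observer's
#' phase-modulated probability. Trials are added until the expected number of
#' targets per (phase bin, position) cell reaches `targets_per_cell`.
#'
#' @param config An [experiment_config()].
#' @param observer An [observer_model()] (positions must match the config's).
#' @param n_subjects Number of simulated subjects.
#' @param targets_per_cell Target count aimed at per phase-bin x position
#'   cell (the original design averages 33).
#' @param staircase_step Staircase step factor.
#' @param start_luminance Staircase starting luminance.
#' @param seed Optional integer seed.
#' @return A list of `subject_dataset` objects, each with elements `subject`,
#'   `entrainment_frequency`, `n_trials`, `targets` (data frame: `subject`,
#'   `trial`, `position_id`, `onset_s`, `luminance`, `phase_rad`, `bin`,
#'   `detected`) and `staircase_trace`.
#' @export
simulate_experiment <- function(config, observer, n_subjects = 1L,
                                targets_per_cell = 33,
                                staircase_step = 1.1,
                                start_luminance = 150,
                                seed = NULL) {
  stopifnot(inherits(config, "experiment_config"),
            inherits(observer, "observer_model"))
  if (!identical(config$positions$id, observer$positions$id)) {
    stop("config and observer use different position layouts", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(n_subjects), function(s) {
    simulate_one_subject(config, observer, subject = sprintf("S%02d", s),
                         targets_per_cell = targets_per_cell,
                         staircase_step = staircase_step,
                         start_luminance = start_luminance)
  })
}

simulate_one_subject <- function(config, observer, subject,
                                 targets_per_cell, staircase_step,
                                 start_luminance) {
  K <- config$binning$n_bins
  pos_ids <- config$positions$id
  P <- length(pos_ids)
  goal <- ceiling(targets_per_cell * K * P)
  f <- config$entrainment_frequency

  trial <- integer(0); onset <- numeric(0); phase <- numeric(0)
  pos <- character(0)
  total <- 0L
  t_idx <- 0L
  while (total < goal) {
    t_idx <- t_idx + 1L
    k <- draw_target_count(config$target_count_probs, 1L)
    times <- draw_target_schedule(k, config)
    offset <- stats::runif(1, -pi, pi)
    trial <- c(trial, rep(t_idx, k))
    onset <- c(onset, times)
    phase <- c(phase, phase_at_time(times, f, offset))
    pos <- c(pos, sample(pos_ids, k, replace = TRUE))
    total <- total + k
  }
  bin <- assign_phase_bin(phase, config$binning)

  # staircase: chronological order within subject, one track per position
  cur <- stats::setNames(rep(start_luminance, P), pos_ids)
  n <- length(onset)
  lum <- numeric(n)
  detected <- logical(n)
  for (i in seq_len(n)) {
    pid <- pos[i]
    lum[i] <- cur[[pid]]
    p <- detection_probability(observer, pid, lum[i], phase[i])
    detected[i] <- stats::runif(1) < p
    cur[[pid]] <- staircase_update(cur[[pid]], detected[i], staircase_step)
  }

  targets <- data.frame(
    subject = subject,
    trial = trial,
    position_id = pos,
    onset_s = onset,
    luminance = lum,
    phase_rad = phase,
    bin = bin,
    detected = detected,
    stringsAsFactors = FALSE
  )
  structure(
    list(
      subject = subject,
      entrainment_frequency = f,
      n_trials = t_idx,
      targets = targets,
      staircase_trace = data.frame(
        position_id = pos, luminance = lum, outcome = detected,
        stringsAsFactors = FALSE
      )
    ),
    class = "subject_dataset"
  )
}

#' @export
print.subject_dataset <- function(x, ...) {
  cat(sprintf("Subject %s: %d trials, %d targets at %.3g Hz, hit rate %.1f%%\n",
              x$subject, x$n_trials, nrow(x$targets),
              x$entrainment_frequency, 100 * mean(x$targets$detected)))
  invisible(x)
}

#' Simulate count data for the SOA masking control
#'
#' In the masking control the disc is flashed once at full luminance and
#' targets appear at signed SOAs spanning one reference cycle. This generator
#' emits per-(subject, position, SOA) binomial counts with a detection rate
#' that may depend on the SOA-equivalent phase (for the null, a constant).
#'
#' @param n_subjects Number of subjects.
#' @param positions Position layout data frame.
#' @param soas_ms SOA grid in milliseconds.
#' @param targets_per_soa Targets per (subject, position, SOA) cell.
#' @param rate Either a single detection rate or a function `f(phi)` giving
#'   the rate at SOA-equivalent phase `phi`.
#' @param reference_period_ms Reference cycle length in ms.
#' @return Data frame with columns `subject`, `position_id`, `soa_ms`, `n`,
#'   `hits`.
#' @export
simulate_soa_dataset <- function(n_subjects = 7L,
                                 positions = positions_exp2(),
                                 soas_ms = c(-50, -37.5, -25, -12.5, 0,
                                             12.5, 25, 37.5, 50),
                                 targets_per_soa = 33L,
                                 rate = 0.5,
                                 reference_period_ms = 100) {
  stopifnot(is.data.frame(positions), "id" %in% names(positions),
            !anyDuplicated(positions$id))
  grid <- expand.grid(
    subject = sprintf("S%02d", seq_len(n_subjects)),
    position_id = positions$id,
    soa_ms = soas_ms,
    stringsAsFactors = FALSE
  )
  phi <- soa_to_phase(grid$soa_ms, reference_period_ms)
  p <- if (is.function(rate)) rate(phi) else rep(rate, nrow(grid))
  stopifnot(all(p >= 0), all(p <= 1))
  grid$n <- as.integer(targets_per_soa)
  grid$hits <- stats::rbinom(nrow(grid), grid$n, p)
  grid
}

#' Simulate count data for the luminance-flash control
#'
#' In the luminance control the disc is flashed once, simultaneously with the
#' target, at one of four luminance levels. This generator emits
#' per-(subject, position, level) binomial counts with a detection rate that
#' may depend on the flash luminance.
#'
#' @param n_subjects Number of subjects.
#' @param positions Position layout data frame.
#' @param levels Flash luminance levels.
#' @param targets_per_level Targets per (subject, position, level) cell.
#' @param rate Either a single rate or a function `f(level)`.
#' @return Data frame with columns `subject`, `position_id`, `level`, `n`,
#'   `hits`.
#' @export
simulate_luminance_dataset <- function(n_subjects = 7L,
                                       positions = positions_exp2(),
                                       levels = c(64, 128, 192, 255),
                                       targets_per_level = 33L,
                                       rate = 0.5) {
  stopifnot(is.data.frame(positions), "id" %in% names(positions),
            !anyDuplicated(positions$id))
  grid <- expand.grid(
    subject = sprintf("S%02d", seq_len(n_subjects)),
    position_id = positions$id,
    level = levels,
    stringsAsFactors = FALSE
  )
  p <- if (is.function(rate)) rate(grid$level) else rep(rate, nrow(grid))
  stopifnot(all(p >= 0), all(p <= 1))
  grid$n <- as.integer(targets_per_level)
  grid$hits <- stats::rbinom(nrow(grid), grid$n, p)
  grid
}
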