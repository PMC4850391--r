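#' Wrap an angle into the principal interval
#'
#' Maps any finite angle (radians) into `[-pi, pi)`. The upper endpoint `pi`
#' is identified with `-pi`, so the image is half-open.
#'
#' @param phi Numeric vector of angles in radians.
#' @return Numeric vector of the same length, in `[-pi, pi)`.
#' @export
#' @examples
#' wrap_phase(c(0, pi, -pi, 3 * pi / 2))
wrap_phase <- function(phi) {
  stopifnot(is.numeric(phi))
  out <- ((phi + pi) %% (2 * pi)) - pi
  # guard against floating fuzz pushing a value to exactly pi
  out[out >= pi] <- -pi
  out
}

#' Oscillation phase at a given time
#'
#' Phase of the entraining luminance oscillation at time `t` for a disc
#' flickering at frequency `f`, with phase zero at the luminance minimum
#' (black). Periodic with period `1/f`.
#'
#' @param t Time in seconds (vectorised).
#' @param f Oscillation frequency in Hz; must be positive.
#' @param phase_offset Phase of the oscillation at `t = 0`, radians.
#' @return Phase in radians, wrapped into `[-pi, pi)`.
#' @export
#' @examples
#' phase_at_time(0.05, 10) # half a 10 Hz period -> -pi
phase_at_time <- function(t, f, phase_offset = 0) {
  if (!is.numeric(f) || length(f) != 1L || !is.finite(f) || f <= 0) {
    stop("`f` must be a single positive frequency in Hz", call. = FALSE)
  }
  wrap_phase(2 * pi * f * t + phase_offset)
}

#' Disc luminance at a given oscillation phase
#'
#' The entraining disc oscillates sinusoidally between black (luminance 0 at
#' phase 0) and white (luminance 255 at phase +/- pi) on an abstract 0-255
#' scale: `L(phi) = 255 * (1 - cos(phi)) / 2`. The function is even in `phi`.
#'
#' @param phi Phase in radians (vectorised; any finite value).
#' @return Luminance on the 0-255 scale.
#' @export
#' @examples
#' luminance_at_phase(c(0, -pi, pi / 2))
luminance_at_phase <- function(phi) {
  stopifnot(is.numeric(phi), all(is.finite(phi)))
  255 * (1 - cos(phi)) / 2
}

#' Construct an equally spaced phase binning
#'
#' Bin centers are `-pi + (k - 1) * 2 * pi / n_bins` for `k = 1..n_bins`
#' (for 8 bins: `-pi, -3pi/4, ..., 3pi/4`), each bin spanning a half-open
#' interval of width `2 * pi / n_bins` around its center.
#'
#' @param n_bins Number of bins (>= 2).
#' @return An object of class `phase_binning` with elements `n_bins`,
#'   `bin_centers` and `bin_width`.
#' @export
phase_binning <- function(n_bins = 8L) {
  n_bins <- as.integer(n_bins)
  if (is.na(n_bins) || n_bins < 2L) {
    stop("`n_bins` must be an integer >= 2", call. = FALSE)
  }
  structure(
    list(
      n_bins = n_bins,
      bin_centers = -pi + (seq_len(n_bins) - 1L) * 2 * pi / n_bins,
      bin_width = 2 * pi / n_bins
    ),
    class = "phase_binning"
  )
}

#' Assign phases to phase bins
#'
#' Each phase is assigned to the bin whose center is nearest; a phase exactly
#' on a bin boundary belongs to the upper bin. The region within half a bin
#' width below `pi` wraps onto the bin centered at `-pi`. The assignment
#' partitions `[-pi, pi)`.
#'
#' @param phi Phases in radians (wrapped internally).
#' @param binning A [phase_binning()] object.
#' @return Integer bin indices in `1..n_bins` (bin `k` has center
#'   `binning$bin_centers[k]`).
#' @export
#' @examples
#' b <- phase_binning(8)
#' assign_phase_bin(c(0, pi / 8, -pi), b)
assign_phase_bin <- function(phi, binning = phase_binning()) {
  stopifnot(inherits(binning, "phase_binning"))
  phi <- wrap_phase(phi)
  u <- (phi + pi) / binning$bin_width
  (as.integer(floor(u + 0.5)) %% binning$n_bins) + 1L
}

#' Map a stimulus-onset asynchrony to an oscillation phase
#'
#' In the masking control, the disc is flashed once and targets appear at
#' SOAs covering one cycle of a reference oscillation (100 ms for an average
#' 10 Hz alpha cycle). The linear map is `phi = 2 * pi * soa / period`, so
#' the nine-point grid `-50, -37.5, ..., +50` ms maps onto
#' `-pi, -3pi/4, ..., +pi`.
#'
#' @param soa Signed SOA in milliseconds; `abs(soa)` must not exceed half the
#'   reference period.
#' @param reference_period_ms Reference cycle length in milliseconds.
#' @return Phase in radians in `[-pi, pi]` (endpoints both reachable; they
#'   denote the same point on the cycle).
#' @export
soa_to_phase <- function(soa, reference_period_ms = 100) {
  stopifnot(is.numeric(soa), is.numeric(reference_period_ms),
            length(reference_period_ms) == 1L, reference_period_ms > 0)
  if (any(abs(soa) > reference_period_ms / 2 + 1e-9)) {
    stop("|soa| must not exceed half the reference period", call. = FALSE)
  }
  2 * pi * soa / reference_period_ms
}

#' Target-position layouts
#'
#' Fixed position constants for the two layouts used in the entrainment
#' experiments. Eccentricities follow cortical magnification so that
#' positions are equally spaced in visual cortex; they are stored as
#' constants, no magnification formula is applied. Exactly one position per
#' layout (the one nearest the oscillating disc, which sits at 7.5 degrees
#' eccentricity in the upper-left quadrant) is flagged `is_adjacent_to_disc`.
#'
#' `positions_exp1()`: 9 positions, 3 per quadrant (upper-left, upper-right,
#' lower-left) at 5.4, 2.9 and 1.5 degrees eccentricity.
#' `positions_exp2()`: 5 positions in the upper-left quadrant, spanning the
#' outer two Exp-1 positions with 3 logarithmically interleaved positions.
#'
#' @return A data frame with columns `id`, `eccentricity` (degrees of visual
#'   angle), `quadrant` and `is_adjacent_to_disc`.
#' @export
positions_exp1 <- function() {
  data.frame(
    id = paste0("P", 1:9),
    eccentricity = c(5.4, 2.9, 1.5, 1.5, 2.9, 5.4, 1.5, 2.9, 5.4),
    quadrant = rep(c("upper_left", "upper_right", "lower_left"), each = 3),
    is_adjacent_to_disc = c(TRUE, rep(FALSE, 8)),
    stringsAsFactors = FALSE
  )
}

#' @rdname positions_exp1
#' @export
positions_exp2 <- function() {
  ecc <- exp(seq(log(5.4), log(2.9), length.out = 5))
  data.frame(
    id = c("I", "II", "III", "IV", "V"),
    eccentricity = round(ecc, 2),
    quadrant = "upper_left",
    is_adjacent_to_disc = c(TRUE, rep(FALSE, 4)),
    stringsAsFactors = FALSE
  )
}

validate_positions <- function(positions) {
  req <- c("id", "eccentricity", "quadrant", "is_adjacent_to_disc")
  if (!is.data.frame(positions) || !all(req %in% names(positions))) {
    stop("`positions` must be a data frame with columns ",
         paste(req, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(positions$id)) {
    stop("position ids must be unique", call. = FALSE)
  }
  if (any(positions$eccentricity <= 0)) {
    stop("eccentricities must be positive", call. = FALSE)
  }
  if (sum(positions$is_adjacent_to_disc) != 1L) {
    stop("exactly one position must be adjacent to the disc", call. = FALSE)
  }
  invisible(positions)
}

#' Experiment configuration
#'
#' Bundles the fixed design constants of one entrainment experiment: trial
#' timing, target-count distribution, phase binning, surrogate count and FDR
#' level, and the position layout.
#'
#' @param entrainment_frequency Disc flicker frequency in Hz (5, ~9.6 for an
#'   individual alpha frequency, or 15 in the original designs).
#' @param trial_duration Trial length in seconds.
#' @param edge_margin Dead time at each end of the trial in which no target
#'   may appear, seconds.
#' @param min_gap Minimum interval between consecutive targets, seconds.
#' @param response_window Time allowed for a detection response, seconds.
#' @param n_phase_bins Number of phase bins.
#' @param target_count_probs Named probability vector over the number of
#'   targets per trial (names are the counts).
#' @param n_surrogates Number of Monte Carlo surrogate datasets.
#' @param fdr_q False-discovery-rate level.
#' @param positions Position layout data frame (see [positions_exp2()]).
#' @param rng_seed Optional integer seed recorded with the configuration.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(entrainment_frequency = 9.6,
                              trial_duration = 6.25,
                              edge_margin = 0.8,
                              min_gap = 0.8,
                              response_window = 0.8,
                              n_phase_bins = 8L,
                              target_count_probs = c(`2` = 0.5, `3` = 0.375, `4` = 0.125),
                              n_surrogates = 50000L,
                              fdr_q = 0.05,
                              positions = positions_exp2(),
                              rng_seed = NULL) {
  stopifnot(entrainment_frequency > 0, trial_duration > 0,
            edge_margin >= 0, min_gap >= 0, response_window > 0,
            fdr_q > 0, fdr_q < 1)
  if (abs(sum(target_count_probs) - 1) > 1e-9 || any(target_count_probs < 0)) {
    stop("`target_count_probs` must be a probability distribution", call. = FALSE)
  }
  if (is.null(names(target_count_probs)) ||
      anyNA(suppressWarnings(as.integer(names(target_count_probs))))) {
    stop("`target_count_probs` must be named by integer target counts", call. = FALSE)
  }
  n_surrogates <- as.integer(n_surrogates)
  if (is.na(n_surrogates) || n_surrogates < 1L) {
    stop("`n_surrogates` must be >= 1", call. = FALSE)
  }
  max_count <- max(as.integer(names(target_count_probs)))
  if (2 * edge_margin + (max_count - 1) * min_gap > trial_duration) {
    stop("infeasible timing: margins plus minimum gaps exceed the trial duration",
         call. = FALSE)
  }
  validate_positions(positions)
  structure(
    list(
      entrainment_frequency = entrainment_frequency,
      trial_duration = trial_duration,
      edge_margin = edge_margin,
      min_gap = min_gap,
      response_window = response_window,
      binning = phase_binning(n_phase_bins),
      target_count_probs = target_count_probs,
      n_surrogates = n_surrogates,
      fdr_q = fdr_q,
      positions = positions,
      rng_seed = rng_seed
    ),
    class = "experiment_config"
  )
}

#' @export
print.experiment_config <- function(x, ...) {
  cat("Entrainment experiment configuration\n")
  cat(sprintf("  frequency: %.3g Hz, trial: %.3g s, margins: %.3g s, min gap: %.3g s\n",
              x$entrainment_frequency, x$trial_duration, x$edge_margin, x$min_gap))
  cat(sprintf("  %d phase bins, %d surrogates, FDR q = %.3g\n",
              x$binning$n_bins, x$n_surrogates, x$fdr_q))
  cat(sprintf("  %d positions (%s adjacent to disc)\n",
              nrow(x$positions), x$positions$id[x$positions$is_adjacent_to_disc]))
  invisible(x)
}
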