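#' Construct a binned-performance object
#'
#' @param position_id Position label (or a pooled label for group averages).
#' @param bin_centers Bin center phases, radians.
#' @param n_targets Targets per bin.
#' @param n_hits Hits per bin.
#' @param hit_rate Hit rate per bin; computed from counts when omitted
#'   (`NA` for empty bins). Group averages carry rates that are means of
#'   subject rates, not ratios of the summed counts.
#' @return An object of class `binned_performance`.
#' @export
binned_performance <- function(position_id, bin_centers, n_targets, n_hits,
                               hit_rate = NULL) {
  stopifnot(length(bin_centers) == length(n_targets),
            length(n_targets) == length(n_hits),
            all(n_targets >= 0), all(n_hits >= 0), all(n_hits <= n_targets))
  if (is.null(hit_rate)) {
    hit_rate <- ifelse(n_targets > 0, n_hits / n_targets, NA_real_)
  }
  structure(
    list(
      position_id = position_id,
      bin_centers = bin_centers,
      n_targets = as.numeric(n_targets),
      n_hits = as.numeric(n_hits),
      hit_rate = hit_rate
    ),
    class = "binned_performance"
  )
}

#' @export
print.binned_performance <- function(x, ...) {
  cat(sprintf("Binned performance at position %s (%d bins, %d targets)\n",
              x$position_id, length(x$bin_centers), sum(x$n_targets)))
  print(data.frame(center = round(x$bin_centers, 3), n = x$n_targets,
                   hits = x$n_hits, rate = round(x$hit_rate, 3)),
        row.names = FALSE)
  invisible(x)
}

#' Phase-binned hit rates for one subject and position
#'
#' Counts targets and hits per phase bin and computes the per-bin hit rate
#' (percentage correct within the bin). Empty bins get an `NA` rate and are
#' flagged downstream.
#'
#' @param dataset A `subject_dataset` from [simulate_experiment()] or
#'   [read_targets()].
#' @param position_id Position to analyse.
#' @param binning A [phase_binning()]; defaults to 8 bins.
#' @return A [binned_performance()] object.
#' @export
bin_performance <- function(dataset, position_id, binning = phase_binning()) {
  stopifnot(inherits(dataset, "subject_dataset"))
  tg <- dataset$targets[dataset$targets$position_id == position_id, ]
  if (nrow(tg) == 0L) {
    stop(sprintf("no targets at position '%s'", position_id), call. = FALSE)
  }
  K <- binning$n_bins
  n <- tabulate(tg$bin, nbins = K)
  h <- tabulate(tg$bin[tg$detected], nbins = K)
  binned_performance(position_id, binning$bin_centers, n, h)
}

# First-harmonic least-squares cosine fit, vectorised over rows of `rates`.
# Solves h ~ b0 + a*cos(phi) + b*sin(phi) by the normal equations shared
# across rows (same centers for every row). For K >= 3 equally spaced
# full-coverage bins this reduces to the Fourier projection
# a = (2/K) sum h cos, b = (2/K) sum h sin; for K = 2 the sine regressor is
# identically collinear and is dropped, which constrains the phase to {0, pi}.
# Returns a data frame with one row per input row.
cosfit_matrix <- function(rates, centers) {
  if (is.null(dim(rates))) rates <- matrix(rates, nrow = 1L)
  stopifnot(ncol(rates) == length(centers))
  X <- cbind(1, cos(centers), sin(centers))
  ss <- colSums(X^2)
  keep <- c(TRUE, ss[2] > 1e-10, ss[3] > 1e-10)
  Xk <- X[, keep, drop = FALSE]
  if (nrow(Xk) < ncol(Xk) || qr(Xk)$rank < ncol(Xk)) {
    stop(sprintf(
      "cosine fit needs at least %d usable bins, got %d", ncol(Xk), nrow(Xk)),
      call. = FALSE)
  }
  coef_k <- rates %*% Xk %*% solve(crossprod(Xk))
  coef <- matrix(0, nrow(rates), 3L)
  coef[, keep] <- coef_k
  a <- coef[, 2]
  b <- coef[, 3]
  amp <- sqrt(a^2 + b^2)
  amp[amp < 1e-12] <- 0 # flat input: round-off only, phase undefined
  phase <- ifelse(amp > 0, wrap_phase(atan2(b, a)), 0)
  data.frame(baseline = coef[, 1], half_amplitude = amp,
             preferred_phase = phase)
}

#' Fit a three-parameter cosine to binned hit rates
#'
#' Fits `rate(phi) = baseline + half_amplitude * cos(phi - preferred_phase)`
#' to the per-bin hit rates by unweighted least squares over the bin means.
#' For equally spaced bins covering the full cycle the solution is the
#' first-harmonic Fourier projection. Bins with no targets are excluded from
#' the fit (with a warning) provided enough usable bins remain to identify
#' the parameters. A flat input is returned with phase 0 and
#' `degenerate = TRUE` so downstream phase tests can exclude it.
#'
#' @param binned A [binned_performance()] object.
#' @return An object of class `cosine_fit` with elements `baseline`,
#'   `half_amplitude`, `preferred_phase` (radians in `[-pi, pi)`),
#'   `peak_to_trough` (`= 2 * half_amplitude`, the quantity conventionally
#'   reported as the oscillatory modulation amplitude), `n_bins_used`,
#'   `n_targets` and `degenerate`.
#' @export
fit_cosine <- function(binned) {
  stopifnot(inherits(binned, "binned_performance"))
  usable <- !is.na(binned$hit_rate)
  if (!all(usable)) {
    warning(sprintf("excluding %d empty bin(s) from the cosine fit",
                    sum(!usable)), call. = FALSE)
  }
  fit <- cosfit_matrix(binned$hit_rate[usable], binned$bin_centers[usable])
  structure(
    list(
      position_id = binned$position_id,
      baseline = fit$baseline,
      half_amplitude = fit$half_amplitude,
      preferred_phase = fit$preferred_phase,
      peak_to_trough = 2 * fit$half_amplitude,
      n_bins_used = sum(usable),
      n_targets = sum(binned$n_targets),
      degenerate = fit$half_amplitude < 1e-9
    ),
    class = "cosine_fit"
  )
}

#' @export
print.cosine_fit <- function(x, ...) {
  cat(sprintf(
    "Cosine fit (%s): baseline %.3f, peak-to-trough %.3f, phase %.3f rad%s\n",
    x$position_id, x$baseline, x$peak_to_trough, x$preferred_phase,
    if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Average binned performance across subjects
#'
#' Fixed-effect group curve: the per-bin rate is the unweighted mean of the
#' subject rates (subjects with an empty bin are ignored in that bin), while
#' per-bin target and hit counts are summed — the summed counts are what the
#' surrogate construction of the Monte Carlo tests needs.
#'
#' @param binned_list List of [binned_performance()] objects with identical
#'   bin centers.
#' @param position_id Label for the resulting group curve; defaults to the
#'   first element's.
#' @return A [binned_performance()] object.
#' @export
group_average_bins <- function(binned_list, position_id = NULL) {
  stopifnot(length(binned_list) >= 1L,
            all(vapply(binned_list, inherits, TRUE, "binned_performance")))
  centers <- binned_list[[1L]]$bin_centers
  same <- vapply(binned_list, function(b) {
    length(b$bin_centers) == length(centers) &&
      max(abs(b$bin_centers - centers)) < 1e-9
  }, TRUE)
  if (!all(same)) stop("subjects use different phase binnings", call. = FALSE)
  rates <- vapply(binned_list, `[[`, numeric(length(centers)), "hit_rate")
  rates <- matrix(rates, nrow = length(centers))
  n <- rowSums(vapply(binned_list, `[[`, numeric(length(centers)), "n_targets"))
  h <- rowSums(vapply(binned_list, `[[`, numeric(length(centers)), "n_hits"))
  binned_performance(
    position_id = position_id %||% binned_list[[1L]]$position_id,
    bin_centers = centers,
    n_targets = n,
    n_hits = h,
    hit_rate = rowMeans(rates, na.rm = TRUE)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Peak-to-trough modulation depth of a cosine fit
#'
#' The fitted performance at the preferred phase minus the fitted performance
#' at the opposite phase, i.e. twice the cosine half-amplitude. This is the
#' quantity conventionally reported as the oscillatory "amplitude" of
#' behavioural modulation.
#'
#' @param fit A [fit_cosine()] result.
#' @return Peak-to-trough modulation as a proportion.
#' @export
modulation_depth <- function(fit) {
  stopifnot(inherits(fit, "cosine_fit"))
  fit$peak_to_trough
}

#' Per-subject, per-position cosine-fit table
#'
#' Bins and fits every (subject, position) combination and returns a tidy
#' table, the input expected by the amplitude ANOVA and post-hoc tests.
#'
#' @param datasets List of `subject_dataset` objects.
#' @param config The [experiment_config()] used to generate them.
#' @param condition Optional condition label (e.g. the entrainment frequency)
#'   stored with every row.
#' @return A data frame with columns `subject`, `condition`, `position_id`,
#'   `baseline`, `half_amplitude`, `peak_to_trough`, `preferred_phase`,
#'   `n_targets`, `degenerate`.
#' @export
fit_table <- function(datasets, config, condition = NA) {
  stopifnot(inherits(config, "experiment_config"))
  rows <- list()
  for (d in datasets) {
    for (pid in config$positions$id) {
      b <- bin_performance(d, pid, config$binning)
      f <- fit_cosine(b)
      rows[[length(rows) + 1L]] <- data.frame(
        subject = d$subject, condition = condition, position_id = pid,
        baseline = f$baseline, half_amplitude = f$half_amplitude,
        peak_to_trough = f$peak_to_trough,
        preferred_phase = f$preferred_phase,
        n_targets = f$n_targets, degenerate = f$degenerate,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}
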