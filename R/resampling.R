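#' @keywords internal
# Surrogate peak-to-trough amplitudes under the equal-performance null.
#
# counts: S x J matrix of per-subject trial counts at the J drawing units
#   (phase bins, or luminance levels for the rearrangement control).
# pooled: length-S vector of each subject's pooled (across-unit) hit rate.
# expand: integer vector of length K mapping each output bin to the drawing
#   unit whose surrogate rate it reuses (identity when J == K).
# For every surrogate, each subject's per-unit hits are Binomial(n, pooled),
# preserving the per-unit trial counts exactly; rates are averaged across
# subjects per bin (subjects with no trials in a unit are skipped in that
# bin), and the group curve is fitted with the same cosine machinery as the
# observed data.
surrogate_amplitudes <- function(counts, pooled, centers, n_surrogates,
                                 expand = NULL) {
  counts <- as.matrix(counts)
  S <- nrow(counts)
  J <- ncol(counts)
  K <- length(centers)
  if (is.null(expand)) {
    stopifnot(J == K)
    expand <- seq_len(K)
  }
  stopifnot(length(pooled) == S, length(expand) == K,
            all(expand >= 1L), all(expand <= J))
  sum_rates <- matrix(0, n_surrogates, K)
  n_sub <- numeric(K)
  for (s in seq_len(S)) {
    ns <- counts[s, ]
    have <- ns > 0
    rate_s <- matrix(NA_real_, n_surrogates, J)
    if (any(have)) {
      draws <- matrix(
        stats::rbinom(n_surrogates * sum(have),
                      size = rep(ns[have], each = n_surrogates),
                      prob = pooled[s]),
        nrow = n_surrogates)
      rate_s[, have] <- sweep(draws, 2L, ns[have], "/")
    }
    re <- rate_s[, expand, drop = FALSE]
    contrib <- have[expand]
    if (any(contrib)) {
      sum_rates[, contrib] <- sum_rates[, contrib] + re[, contrib, drop = FALSE]
      n_sub <- n_sub + as.numeric(contrib)
    }
  }
  usable <- n_sub > 0
  group <- sweep(sum_rates[, usable, drop = FALSE], 2L, n_sub[usable], "/")
  2 * cosfit_matrix(group, centers[usable])$half_amplitude
}

mc_result <- function(test, observed_statistic, surrogates, n_surrogates,
                      position_id = NA_character_) {
  r <- sum(surrogates >= observed_statistic)
  structure(
    list(
      test = test,
      position_id = position_id,
      observed_statistic = observed_statistic,
      n_surrogates = n_surrogates,
      p_raw = r / n_surrogates,
      p_conservative = (r + 1) / (n_surrogates + 1),
      significant_fdr = NA,
      surrogate_quantiles = stats::quantile(
        surrogates, c(0.5, 0.9, 0.95, 0.99), names = TRUE)
    ),
    class = "mc_result"
  )
}

#' @export
print.mc_result <- function(x, ...) {
  cat(sprintf(
    "Monte Carlo %s test%s: observed %.4f, p = %.4g (%d surrogates%s)\n",
    x$test,
    if (!is.na(x$position_id)) sprintf(" [%s]", x$position_id) else "",
    x$observed_statistic, x$p_raw, x$n_surrogates,
    if (!is.na(x$significant_fdr)) {
      sprintf("; FDR %s", if (x$significant_fdr) "significant" else "n.s.")
    } else ""))
  invisible(x)
}

#' Monte Carlo test for oscillatory amplitude
#'
#' Tests whether the group-average phase-binned hit-rate curve has a larger
#' first-harmonic (cosine) amplitude than expected if performance were equal
#' across phase bins. For each surrogate dataset and each subject, every
#' trial's outcome is redrawn as Bernoulli with that subject's pooled
#' across-bin hit rate, preserving the per-bin trial counts exactly;
#' surrogate rates are averaged across subjects, fitted with the same cosine
#' machinery as the observed data, and the observed peak-to-trough amplitude
#' is compared against the surrogate distribution. The p-value is the
#' proportion of surrogate amplitudes greater than or equal to the observed
#' one (it can be exactly 0; a conservative `(r + 1) / (n + 1)` version is
#' also reported). This is a fixed-effect test: the statistic is a property
#' of the grand average across subjects.
#'
#' @param binned_list List of per-subject [binned_performance()] objects for
#'   one position (identical binning across subjects).
#' @param n_surrogates Number of surrogate datasets (the reference analysis
#'   uses 50,000).
#' @param seed Optional integer seed.
#' @return An object of class `mc_result` with elements
#'   `observed_statistic` (peak-to-trough amplitude of the group fit),
#'   `p_raw`, `p_conservative`, `n_surrogates`, `surrogate_quantiles`.
#' @export
mc_amplitude_test <- function(binned_list, n_surrogates = 50000L,
                              seed = NULL) {
  if (inherits(binned_list, "binned_performance")) {
    binned_list <- list(binned_list)
  }
  stopifnot(length(binned_list) >= 1L,
            all(vapply(binned_list, inherits, TRUE, "binned_performance")))
  n_surrogates <- as.integer(n_surrogates)
  stopifnot(n_surrogates >= 1L)
  if (!is.null(seed)) set.seed(seed)

  centers <- binned_list[[1L]]$bin_centers
  counts <- t(vapply(binned_list, `[[`, numeric(length(centers)), "n_targets"))
  hits <- t(vapply(binned_list, `[[`, numeric(length(centers)), "n_hits"))
  tot <- rowSums(counts)
  if (any(tot == 0)) stop("a subject has no trials at this position", call. = FALSE)
  pooled <- rowSums(hits) / tot

  grp <- group_average_bins(binned_list)
  usable <- !is.na(grp$hit_rate)
  obs <- 2 * cosfit_matrix(grp$hit_rate[usable], centers[usable])$half_amplitude
  surr <- surrogate_amplitudes(counts, pooled, centers, n_surrogates)
  mc_result("amplitude", obs, surr, n_surrogates,
            position_id = as.character(grp$position_id))
}

#' Monte Carlo test for a preferred-phase difference
#'
#' Tests whether the preferred phases of two locations' group-average curves
#' differ, against the null that both locations oscillate with the same
#' maximal phase. Surrogate pairs preserve each location's per-bin summed
#' trial counts; every trial's outcome is Bernoulli with a per-bin rate equal
#' to the average of the two locations' observed rates in that bin. The
#' statistic is the absolute circular distance between fitted preferred
#' phases (principal value, in `[0, pi]`); the p-value is the proportion of
#' surrogate distances greater than or equal to the observed one.
#'
#' @param binned_a,binned_b Group-level [binned_performance()] objects (from
#'   [group_average_bins()], so per-bin counts are summed across subjects)
#'   with identical binning. Both fits must be non-degenerate.
#' @param n_surrogates Number of surrogate pairs.
#' @param seed Optional integer seed.
#' @return An object of class `mc_result` with the observed circular
#'   distance (radians) as `observed_statistic`.
#' @export
mc_phase_difference_test <- function(binned_a, binned_b,
                                     n_surrogates = 50000L, seed = NULL) {
  stopifnot(inherits(binned_a, "binned_performance"),
            inherits(binned_b, "binned_performance"))
  n_surrogates <- as.integer(n_surrogates)
  stopifnot(n_surrogates >= 1L)
  centers <- binned_a$bin_centers
  if (length(binned_b$bin_centers) != length(centers) ||
      max(abs(binned_b$bin_centers - centers)) > 1e-9) {
    stop("the two locations use different phase binnings", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)

  usable <- !is.na(binned_a$hit_rate) & !is.na(binned_b$hit_rate) &
    binned_a$n_targets > 0 & binned_b$n_targets > 0
  fa <- cosfit_matrix(binned_a$hit_rate[usable], centers[usable])
  fb <- cosfit_matrix(binned_b$hit_rate[usable], centers[usable])
  if (fa$half_amplitude < 1e-9 || fb$half_amplitude < 1e-9) {
    stop("degenerate (flat) fit at one of the locations; phase is undefined",
         call. = FALSE)
  }
  obs <- abs(wrap_phase(fa$preferred_phase - fb$preferred_phase))

  p_common <- (binned_a$hit_rate[usable] + binned_b$hit_rate[usable]) / 2
  ctr <- centers[usable]
  draw_phases <- function(n_bins_counts) {
    K <- length(ctr)
    draws <- matrix(
      stats::rbinom(n_surrogates * K,
                    size = rep(n_bins_counts, each = n_surrogates),
                    prob = rep(p_common, each = n_surrogates)),
      nrow = n_surrogates)
    rates <- sweep(draws, 2L, n_bins_counts, "/")
    cosfit_matrix(rates, ctr)$preferred_phase
  }
  pa <- draw_phases(binned_a$n_targets[usable])
  pb <- draw_phases(binned_b$n_targets[usable])
  surr <- abs(wrap_phase(pa - pb))
  res <- mc_result("phase-difference", obs, surr, n_surrogates,
                   position_id = paste(binned_a$position_id,
                                       binned_b$position_id, sep = " vs "))
  res
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up FDR control at level `q`. Flags are monotone: rejecting a p-value
#' implies rejecting all smaller ones.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @param q FDR level.
#' @return A data frame with columns `p_raw`, `p_adj` and `significant`.
#' @export
fdr_adjust <- function(p_values, q = 0.05) {
  stopifnot(is.numeric(p_values), q > 0, q < 1)
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p_adj <- stats::p.adjust(p_values, method = "BH")
  data.frame(p_raw = p_values, p_adj = p_adj, significant = p_adj <= q)
}

#' Position-wise amplitude tests with FDR correction
#'
#' Runs [mc_amplitude_test()] at every position of the layout and corrects
#' the resulting p-values across positions with [fdr_adjust()].
#'
#' @param datasets List of `subject_dataset` objects.
#' @param config The [experiment_config()].
#' @param n_surrogates Surrogates per test; defaults to the config value.
#' @param seed Optional integer seed.
#' @return A data frame with one row per position: `position_id`,
#'   `peak_to_trough`, `preferred_phase`, `p_raw`, `p_adj`, `significant`,
#'   `n_surrogates`.
#' @export
amplitude_tests_by_position <- function(datasets, config,
                                        n_surrogates = NULL, seed = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  n_surrogates <- n_surrogates %||% config$n_surrogates
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(config$positions$id, function(pid) {
    binned <- lapply(datasets, bin_performance, position_id = pid,
                     binning = config$binning)
    grp <- group_average_bins(binned)
    fit <- fit_cosine(grp)
    mc <- mc_amplitude_test(binned, n_surrogates = n_surrogates)
    data.frame(position_id = pid,
               peak_to_trough = fit$peak_to_trough,
               preferred_phase = fit$preferred_phase,
               p_raw = mc$p_raw, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  adj <- fdr_adjust(out$p_raw, config$fdr_q)
  out$p_adj <- adj$p_adj
  out$significant <- adj$significant
  out$n_surrogates <- n_surrogates
  out
}

#' Pairwise preferred-phase difference tests with FDR correction
#'
#' Runs [mc_phase_difference_test()] for the requested position pairs
#' (default: all pairs) on the group-average curves and corrects across
#' pairs with [fdr_adjust()]. Pairs whose fit is degenerate at either
#' location are reported with `NA` p-values and excluded from the correction.
#'
#' @param datasets List of `subject_dataset` objects.
#' @param config The [experiment_config()].
#' @param pairs Optional list of 2-element character vectors of position ids.
#' @param n_surrogates Surrogates per test; defaults to the config value.
#' @param seed Optional integer seed.
#' @return A data frame with one row per pair: `position_a`, `position_b`,
#'   `phase_difference` (radians), `p_raw`, `p_adj`, `significant`.
#' @export
phase_difference_tests <- function(datasets, config, pairs = NULL,
                                   n_surrogates = NULL, seed = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  n_surrogates <- n_surrogates %||% config$n_surrogates
  if (!is.null(seed)) set.seed(seed)
  ids <- config$positions$id
  if (is.null(pairs)) {
    pairs <- utils::combn(ids, 2L, simplify = FALSE)
  }
  grp <- lapply(ids, function(pid) {
    group_average_bins(lapply(datasets, bin_performance, position_id = pid,
                              binning = config$binning))
  })
  names(grp) <- ids
  rows <- lapply(pairs, function(pr) {
    res <- tryCatch(
      mc_phase_difference_test(grp[[pr[1L]]], grp[[pr[2L]]],
                               n_surrogates = n_surrogates),
      error = function(e) NULL)
    data.frame(
      position_a = pr[1L], position_b = pr[2L],
      phase_difference = if (is.null(res)) NA_real_ else res$observed_statistic,
      p_raw = if (is.null(res)) NA_real_ else res$p_raw,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- NA_real_
  out$significant <- NA
  ok <- !is.na(out$p_raw)
  if (any(ok)) {
    adj <- fdr_adjust(out$p_raw[ok], config$fdr_q)
    out$p_adj[ok] <- adj$p_adj
    out$significant[ok] <- adj$significant
  }
  out$n_surrogates <- n_surrogates
  out
}
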