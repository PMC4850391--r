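#' Analyse the SOA masking control
#'
#' The masking control replaces the oscillating disc by a single full-
#' luminance flash and probes detection at signed SOAs spanning one
#' reference cycle. Each SOA is mapped to its phase equivalent
#' (see [soa_to_phase()]); the two endpoint SOAs (+/- half a period) denote
#' the same point on the cycle and are merged into the single `-pi` bin
#' before fitting. The resulting per-position curves are fitted and tested
#' with exactly the same cosine and Monte Carlo machinery as the entrainment
#' data, with FDR correction across positions.
#'
#' @param soa_df Data frame with columns `subject`, `position_id`, `soa_ms`,
#'   `n`, `hits` (see [simulate_soa_dataset()]). Every (subject, position)
#'   must cover the full SOA grid.
#' @param n_surrogates Surrogates per position.
#' @param fdr_q FDR level across positions.
#' @param reference_period_ms Reference cycle length in ms.
#' @param seed Optional integer seed.
#' @return A list with `summary` (per-position data frame: `position_id`,
#'   `peak_to_trough`, `preferred_phase`, `p_raw`, `p_adj`, `significant`)
#'   and `per_position` (named list of `fit`, `mc`, `binned` objects).
#' @export
analyze_soa_control <- function(soa_df, n_surrogates = 50000L, fdr_q = 0.05,
                                reference_period_ms = 100, seed = NULL) {
  req <- c("subject", "position_id", "soa_ms", "n", "hits")
  if (!is.data.frame(soa_df) || !all(req %in% names(soa_df))) {
    stop("`soa_df` must contain columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  # the design grid: 9 equally spaced SOAs spanning one full cycle
  grid <- seq(-reference_period_ms / 2, reference_period_ms / 2,
              length.out = 9L)
  if (!setequal(round(unique(soa_df$soa_ms), 6), round(grid, 6))) {
    stop("missing or duplicated SOA levels: the design needs the 9-point ",
         "grid spanning one reference cycle (",
         paste(grid, collapse = ", "), " ms)", call. = FALSE)
  }
  # every (subject, position) must carry every SOA level exactly once
  tab <- table(soa_df$subject, soa_df$position_id, soa_df$soa_ms)
  if (any(tab != 1L)) {
    stop("missing or duplicated SOA levels: every (subject, position) must ",
         "cover the full SOA grid once", call. = FALSE)
  }
  centers_all <- wrap_phase(soa_to_phase(soa_df$soa_ms, reference_period_ms))
  soa_df$center <- round(centers_all, 10)
  centers <- sort(unique(soa_df$center))

  positions <- unique(soa_df$position_id)
  per_position <- list()
  rows <- list()
  for (pid in positions) {
    sub <- soa_df[soa_df$position_id == pid, ]
    binned <- lapply(split(sub, sub$subject), function(d) {
      agg_n <- tapply(d$n, d$center, sum)
      agg_h <- tapply(d$hits, d$center, sum)
      o <- match(as.character(centers), names(agg_n))
      binned_performance(pid, centers, as.numeric(agg_n[o]),
                         as.numeric(agg_h[o]))
    })
    grp <- group_average_bins(binned)
    fit <- fit_cosine(grp)
    mc <- mc_amplitude_test(binned, n_surrogates = n_surrogates)
    per_position[[pid]] <- list(fit = fit, mc = mc, binned = grp)
    rows[[pid]] <- data.frame(
      position_id = pid, peak_to_trough = fit$peak_to_trough,
      preferred_phase = fit$preferred_phase, p_raw = mc$p_raw,
      stringsAsFactors = FALSE)
  }
  summary <- do.call(rbind, rows)
  adj <- fdr_adjust(summary$p_raw, fdr_q)
  summary$p_adj <- adj$p_adj
  summary$significant <- adj$significant
  rownames(summary) <- NULL
  list(summary = summary, per_position = per_position)
}

# the fixed level-to-bin assignment of the luminance-flash control:
# bins at -pi, -3pi/4, -pi/2, -pi/4, 0, pi/4, pi/2, 3pi/4 reuse the
# performance measured at flash luminance 255, 192, 128, 64, 64, 64, 128,
# 192 respectively (the zero-luminance bin at phase 0 cannot be measured on
# a black background and borrows its nearest neighbour, level 64).
luminance_bin_map <- function() {
  list(
    centers = c(-pi, -3 * pi / 4, -pi / 2, -pi / 4, 0, pi / 4, pi / 2,
                3 * pi / 4),
    source_level = c(255, 192, 128, 64, 64, 64, 128, 192)
  )
}

#' Rearrange luminance-flash performance into emulated phase bins
#'
#' The luminance control flashes the disc at four luminance levels (64, 128,
#' 192, 255) simultaneously with the target. To compare its effect with the
#' entrainment experiments, the per-level hit rates are rearranged into an
#' 8-bin emulated oscillation cycle using the levels the oscillating disc
#' displays at those phases (each level serves two mirror-image phases, and
#' the unmeasurable zero-luminance bin borrows the level-64 performance).
#' The emulated curve is even in phase by construction, so the fitted
#' preferred phase is always 0 or pi. The curve is fitted and tested with
#' the same machinery as the entrainment data; surrogates are drawn at the
#' level of the four measured luminances and rearranged identically.
#'
#' @param lum_df Data frame with columns `subject`, `level`, `n`, `hits` for
#'   one target position; all four levels must be present for every subject.
#' @param n_surrogates Surrogates for the amplitude test.
#' @param position_id Label attached to the result.
#' @param seed Optional integer seed.
#' @return A list with `binned` (the emulated group [binned_performance()]),
#'   `fit` (its [fit_cosine()]) and `mc` (the amplitude `mc_result`).
#' @export
rearrange_luminance_to_bins <- function(lum_df, n_surrogates = 50000L,
                                        position_id = "P", seed = NULL) {
  req <- c("subject", "level", "n", "hits")
  if (!is.data.frame(lum_df) || !all(req %in% names(lum_df))) {
    stop("`lum_df` must contain columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  levels_needed <- c(64, 128, 192, 255)
  tab <- table(lum_df$subject, lum_df$level)
  if (!all(as.character(levels_needed) %in% colnames(tab)) || any(tab != 1L)) {
    stop("every subject must carry each luminance level 64, 128, 192, 255 ",
         "exactly once", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  map <- luminance_bin_map()
  expand <- match(map$source_level, levels_needed)

  subjects <- unique(lum_df$subject)
  counts <- matrix(0, length(subjects), length(levels_needed),
                   dimnames = list(subjects, levels_needed))
  hits <- counts
  for (i in seq_along(subjects)) {
    d <- lum_df[lum_df$subject == subjects[i], ]
    o <- match(levels_needed, d$level)
    counts[i, ] <- d$n[o]
    hits[i, ] <- d$hits[o]
  }
  rate_lvl <- hits / counts

  binned <- lapply(seq_along(subjects), function(i) {
    binned_performance(position_id, map$centers,
                       counts[i, expand], hits[i, expand])
  })
  grp <- group_average_bins(binned, position_id = position_id)
  fit <- fit_cosine(grp)
  obs <- fit$peak_to_trough
  pooled <- rowSums(hits) / rowSums(counts)
  surr <- surrogate_amplitudes(counts, pooled, map$centers,
                               as.integer(n_surrogates), expand = expand)
  mc <- mc_result("amplitude (emulated luminance cycle)", obs, surr,
                  as.integer(n_surrogates), position_id = position_id)
  list(binned = grp, fit = fit, mc = mc)
}

#' Analyse the luminance-flash control across positions
#'
#' Applies [rearrange_luminance_to_bins()] at every position and corrects
#' the amplitude p-values across positions with [fdr_adjust()].
#'
#' @param lum_df Data frame with columns `subject`, `position_id`, `level`,
#'   `n`, `hits` (see [simulate_luminance_dataset()]).
#' @param n_surrogates Surrogates per position.
#' @param fdr_q FDR level.
#' @param seed Optional integer seed.
#' @return A list with `summary` (per-position data frame) and
#'   `per_position` (named list of [rearrange_luminance_to_bins()] results).
#' @export
analyze_luminance_control <- function(lum_df, n_surrogates = 50000L,
                                      fdr_q = 0.05, seed = NULL) {
  stopifnot("position_id" %in% names(lum_df))
  if (!is.null(seed)) set.seed(seed)
  positions <- unique(lum_df$position_id)
  per_position <- list()
  rows <- list()
  for (pid in positions) {
    res <- rearrange_luminance_to_bins(
      lum_df[lum_df$position_id == pid,
             c("subject", "level", "n", "hits")],
      n_surrogates = n_surrogates, position_id = pid)
    per_position[[pid]] <- res
    rows[[pid]] <- data.frame(
      position_id = pid, peak_to_trough = res$fit$peak_to_trough,
      preferred_phase = res$fit$preferred_phase, p_raw = res$mc$p_raw,
      stringsAsFactors = FALSE)
  }
  summary <- do.call(rbind, rows)
  adj <- fdr_adjust(summary$p_raw, fdr_q)
  summary$p_adj <- adj$p_adj
  summary$significant <- adj$significant
  rownames(summary) <- NULL
  list(summary = summary, per_position = per_position)
}
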