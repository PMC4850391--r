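#' Two-way fixed-effects ANOVA on fitted oscillation amplitudes
#'
#' Decomposes per-subject peak-to-trough amplitudes by two crossed factors
#' (typically entrainment frequency and target position) in a balanced
#' fixed-effects design, returning the F statistic and p-value for each main
#' effect and the interaction.
#'
#' @param table Data frame with columns `condition`, `position_id` and
#'   `peak_to_trough` (see [fit_table()]).
#' @return A list of class `anova_amplitude` with a data frame `table`
#'   (rows: condition, position, interaction, residuals; columns: `df`,
#'   `sum_sq`, `F`, `p`) and the total sum of squares `ss_total`.
#' @export
two_way_anova_amplitude <- function(table) {
  req <- c("condition", "position_id", "peak_to_trough")
  if (!is.data.frame(table) || !all(req %in% names(table))) {
    stop("`table` must contain columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  cond <- factor(table$condition)
  pos <- factor(table$position_id)
  if (nlevels(cond) < 2L || nlevels(pos) < 2L) {
    stop("each factor needs at least 2 levels", call. = FALSE)
  }
  cell_n <- table(cond, pos)
  if (any(cell_n < 2L)) {
    stop("each condition x position cell needs at least 2 replicates",
         call. = FALSE)
  }
  if (length(unique(as.vector(cell_n))) != 1L) {
    stop("design must be balanced (equal cell counts)", call. = FALSE)
  }
  y <- table$peak_to_trough
  fit <- stats::aov(y ~ cond * pos)
  sm <- summary(fit)[[1L]]
  out <- data.frame(
    term = c("condition", "position", "interaction", "residuals"),
    df = sm[["Df"]],
    sum_sq = sm[["Sum Sq"]],
    F = sm[["F value"]],
    p = sm[["Pr(>F)"]]
  )
  structure(
    list(table = out, ss_total = sum(sm[["Sum Sq"]])),
    class = "anova_amplitude"
  )
}

#' @export
print.anova_amplitude <- function(x, ...) {
  cat("Two-way fixed-effects ANOVA on peak-to-trough amplitudes\n")
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Post-hoc pairwise comparisons of amplitude groups
#'
#' Welch two-sample t-tests for the requested group pairs with
#' Benjamini-Hochberg correction over the pair family (`method = "fdr"`), or
#' Tukey's HSD on a one-way layout (`method = "tukey"`, studentized-range
#' p-values from [stats::TukeyHSD()]).
#'
#' @param table Data frame containing the grouping and value columns.
#' @param group Name of the grouping column.
#' @param value Name of the value column.
#' @param pairs Optional list of 2-element character vectors of group
#'   levels; defaults to all pairs.
#' @param method `"fdr"` or `"tukey"`.
#' @param q FDR level used for the significance flag (fdr method).
#' @return Data frame with one row per pair: `group_a`, `group_b`,
#'   `statistic` (Welch t, or the group-mean difference for Tukey), `p_raw`
#'   (`NA` for Tukey), `p_adj`, `significant`, `method`.
#' @export
posthoc_pairwise <- function(table, group = "condition",
                             value = "peak_to_trough", pairs = NULL,
                             method = c("fdr", "tukey"), q = 0.05) {
  method <- match.arg(method)
  stopifnot(is.data.frame(table), group %in% names(table),
            value %in% names(table))
  g <- factor(table[[group]])
  y <- table[[value]]
  if (any(table(g) < 2L)) {
    stop("every group needs at least 2 values", call. = FALSE)
  }
  if (is.null(pairs)) {
    pairs <- utils::combn(levels(g), 2L, simplify = FALSE)
  }
  if (method == "fdr") {
    rows <- lapply(pairs, function(pr) {
      tt <- stats::t.test(y[g == pr[1L]], y[g == pr[2L]])
      data.frame(group_a = pr[1L], group_b = pr[2L],
                 statistic = unname(tt$statistic),
                 p_raw = tt$p.value, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    adj <- fdr_adjust(out$p_raw, q)
    out$p_adj <- adj$p_adj
    out$significant <- adj$significant
  } else {
    hsd <- stats::TukeyHSD(stats::aov(y ~ g))$g
    key <- paste(vapply(pairs, `[`, "", 2L), vapply(pairs, `[`, "", 1L),
                 sep = "-")
    alt_key <- paste(vapply(pairs, `[`, "", 1L), vapply(pairs, `[`, "", 2L),
                     sep = "-")
    idx <- ifelse(key %in% rownames(hsd), key, alt_key)
    out <- data.frame(
      group_a = vapply(pairs, `[`, "", 1L),
      group_b = vapply(pairs, `[`, "", 2L),
      statistic = hsd[idx, "diff"],
      p_raw = NA_real_,
      p_adj = hsd[idx, "p adj"],
      stringsAsFactors = FALSE)
    out$significant <- out$p_adj <= q
    rownames(out) <- NULL
  }
  out$method <- method
  out
}

# Fisher's approximation to the inverse of A(kappa) = I1(kappa)/I0(kappa),
# the standard estimator of the von Mises concentration from the mean
# resultant length.
a1inv <- function(r) {
  if (r >= 0 && r < 0.53) {
    2 * r + r^3 + 5 * r^5 / 6
  } else if (r < 0.85) {
    -0.4 + 1.39 * r + 0.43 / (1 - r)
  } else {
    1 / (r^3 - 4 * r^2 + 3 * r)
  }
}

#' Watson-Williams test for equal circular means
#'
#' Parametric multi-sample comparison of mean directions, assuming von Mises
#' samples with a common, adequately large concentration. Uses the standard
#' F statistic with the `1 + 3 / (8 * kappa)` correction, with the
#' concentration estimated from the within-group mean resultant length. A
#' warning is issued when that resultant length falls below 0.45, where the
#' test is unreliable.
#'
#' @param samples List of numeric vectors of angles in radians, one per
#'   group; each group needs at least 3 angles.
#' @return A list of class `watson_williams` with elements `statistic` (F),
#'   `df1`, `df2`, `p_value`, `kappa`, `r_within` and the per-group mean
#'   directions.
#' @export
watson_williams <- function(samples) {
  stopifnot(is.list(samples), length(samples) >= 2L)
  if (any(vapply(samples, length, 1L) < 3L)) {
    stop("every group needs at least 3 angles", call. = FALSE)
  }
  r <- length(samples)
  n_i <- vapply(samples, length, 1L)
  C_i <- vapply(samples, function(x) sum(cos(x)), 1)
  S_i <- vapply(samples, function(x) sum(sin(x)), 1)
  R_i <- sqrt(C_i^2 + S_i^2)
  N <- sum(n_i)
  R <- sqrt(sum(C_i)^2 + sum(S_i)^2)
  sum_Ri <- sum(R_i)
  r_within <- sum_Ri / N
  if (r_within < 0.45) {
    warning("mean resultant length below 0.45; the Watson-Williams test ",
            "is unreliable for such dispersed samples", call. = FALSE)
  }
  kappa <- a1inv(r_within)
  correction <- 1 + 3 / (8 * kappa)
  denom <- N - sum_Ri
  F_stat <- if (denom <= 0) Inf else {
    correction * ((N - r) * (sum_Ri - R)) / ((r - 1) * denom)
  }
  F_stat <- max(F_stat, 0)
  structure(
    list(
      statistic = F_stat,
      df1 = r - 1L,
      df2 = N - r,
      p_value = stats::pf(F_stat, r - 1L, N - r, lower.tail = FALSE),
      kappa = kappa,
      r_within = r_within,
      group_means = atan2(S_i, C_i)
    ),
    class = "watson_williams"
  )
}

#' @export
print.watson_williams <- function(x, ...) {
  cat(sprintf("Watson-Williams test: F(%d, %d) = %.4g, p = %.4g\n",
              x$df1, x$df2, x$statistic, x$p_value))
  invisible(x)
}

#' Pearson chi-square test on a 2x2 contingency table
#'
#' Pearson's chi-square without continuity correction (1 degree of freedom),
#' e.g. for comparing the proportion of observers showing a significant
#' behavioural oscillation between an entrainment condition and a control.
#'
#' @param counts 2x2 matrix of non-negative integer counts with positive
#'   margins.
#' @return A list with `statistic`, `df`, `p_value` and `expected`.
#' @export
chi_square_2x2 <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2L, 2L))) {
    stop("`counts` must be a 2x2 matrix", call. = FALSE)
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("all table margins must be positive", call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(statistic = unname(ct$statistic), df = 1L,
       p_value = ct$p.value, expected = ct$expected)
}
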