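#' Run the full analysis pipeline
#'
#' Executes simulate -> bin/fit -> Monte Carlo tests -> controls ->
#' cross-condition comparisons -> report from a single YAML configuration,
#' writing tab-separated result tables, a human-readable report and a JSON
#' run manifest (config snapshot, every seed consumed, output files,
#' software version, per-stage timing) into `outdir`. Identical seeds yield
#' byte-identical result tables.
#'
#' When the run block lists several entrainment `frequencies`, one dataset
#' is simulated per frequency and the compare stage adds the two-way
#' frequency x position ANOVA on fitted amplitudes, post-hoc t-tests between
#' frequencies and a Watson-Williams comparison of the per-subject phase
#' differences (adjacent position vs the others) across frequencies.
#'
#' @param config_path Path to the YAML configuration (see [read_config()]).
#' @param outdir Output directory (created if needed).
#' @param seed Optional integer overriding the configured seed.
#' @param n_surrogates Optional integer overriding the configured surrogate
#'   count.
#' @param stages Character vector of stages to run; any of `"simulate"`,
#'   `"analyze"`, `"controls"`, `"compare"`, `"report"`, or `"all"`. Stages
#'   later in the chain re-read the tables earlier stages wrote, so partial
#'   runs need the earlier outputs present.
#' @return Invisibly, a list with the manifest and the paths of all written
#'   tables.
#' @export
run_pipeline <- function(config_path, outdir, seed = NULL,
                         n_surrogates = NULL, stages = "all") {
  all_stages <- c("simulate", "analyze", "controls", "compare", "report")
  if (identical(stages, "all")) stages <- all_stages
  stopifnot(all(stages %in% all_stages))
  cfg <- read_config(config_path)
  config <- cfg$config
  observer <- cfg$observer
  run <- cfg$run
  if (!is.null(seed)) run$seed <- as.integer(seed)
  n_surrogates <- as.integer(n_surrogates %||% config$n_surrogates)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  set.seed(run$seed)
  stage_seeds <- stats::setNames(sample.int(.Machine$integer.max, 5L),
                                 all_stages)
  outputs <- character(0)
  timing <- list()
  freqs <- run$frequencies
  freq_label <- function(f) gsub("[^0-9A-Za-z.]", "_", format(f))
  targets_path <- function(f) {
    file.path(outdir, sprintf("targets_%shz.tsv", freq_label(f)))
  }
  config_at <- function(f) {
    config$entrainment_frequency <- f
    config
  }

  if ("simulate" %in% stages) {
    t0 <- proc.time()[["elapsed"]]
    set.seed(stage_seeds[["simulate"]])
    for (f in freqs) {
      datasets <- simulate_experiment(
        config_at(f), observer, n_subjects = run$n_subjects,
        targets_per_cell = run$targets_per_cell,
        staircase_step = run$staircase_step,
        start_luminance = run$start_luminance)
      write_targets(datasets, targets_path(f), config_at(f))
      outputs <- c(outputs, targets_path(f))
    }
    timing$simulate <- proc.time()[["elapsed"]] - t0
  }

  if ("analyze" %in% stages) {
    t0 <- proc.time()[["elapsed"]]
    set.seed(stage_seeds[["analyze"]])
    fits <- list(); amps <- list(); phds <- list()
    for (f in freqs) {
      datasets <- read_targets(targets_path(f), config_at(f))
      fits[[length(fits) + 1L]] <-
        fit_table(datasets, config_at(f), condition = f)
      a <- amplitude_tests_by_position(datasets, config_at(f),
                                       n_surrogates = n_surrogates)
      a$condition <- f
      amps[[length(amps) + 1L]] <- a
      p <- phase_difference_tests(datasets, config_at(f),
                                  n_surrogates = n_surrogates)
      p$condition <- f
      phds[[length(phds) + 1L]] <- p
    }
    paths <- c(fits = file.path(outdir, "fits.tsv"),
               amps = file.path(outdir, "amplitude_tests.tsv"),
               phds = file.path(outdir, "phase_differences.tsv"))
    utils::write.table(do.call(rbind, fits), paths[["fits"]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(do.call(rbind, amps), paths[["amps"]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(do.call(rbind, phds), paths[["phds"]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    outputs <- c(outputs, unname(paths))
    timing$analyze <- proc.time()[["elapsed"]] - t0
  }

  if ("controls" %in% stages) {
    t0 <- proc.time()[["elapsed"]]
    set.seed(stage_seeds[["controls"]])
    # masking control: single full-luminance flash at signed SOAs, no
    # entrainment -> SOA-independent detection near the staircase target
    soa_df <- simulate_soa_dataset(
      n_subjects = run$n_subjects, positions = config$positions,
      targets_per_soa = run$targets_per_cell, rate = 0.5)
    soa_res <- analyze_soa_control(soa_df, n_surrogates = n_surrogates,
                                   fdr_q = config$fdr_q)
    # luminance control: flash luminance drives detection strongly at the
    # adjacent position, weakly elsewhere
    adj <- config$positions$id[config$positions$is_adjacent_to_disc]
    lum_parts <- lapply(seq_len(nrow(config$positions)), function(i) {
      pid <- config$positions$id[i]
      gain <- if (pid == adj) 0.4 else 0.08
      simulate_luminance_dataset(
        n_subjects = run$n_subjects,
        positions = config$positions[i, , drop = FALSE],
        targets_per_level = run$targets_per_cell,
        rate = function(level) 0.5 + gain * (level - 159.75) / 191)
    })
    lum_df <- do.call(rbind, lum_parts)
    lum_res <- analyze_luminance_control(lum_df, n_surrogates = n_surrogates,
                                         fdr_q = config$fdr_q)
    paths <- c(soa = file.path(outdir, "soa_control.tsv"),
               lum = file.path(outdir, "luminance_control.tsv"))
    utils::write.table(soa_res$summary, paths[["soa"]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(lum_res$summary, paths[["lum"]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    outputs <- c(outputs, unname(paths))
    timing$controls <- proc.time()[["elapsed"]] - t0
  }

  if ("compare" %in% stages) {
    t0 <- proc.time()[["elapsed"]]
    set.seed(stage_seeds[["compare"]])
    rows <- list()
    if (length(freqs) >= 2L) {
      fits <- utils::read.delim(file.path(outdir, "fits.tsv"),
                                stringsAsFactors = FALSE)
      aov2 <- two_way_anova_amplitude(fits)
      for (i in 1:3) {
        rows[[length(rows) + 1L]] <- data.frame(
          test = paste0("two-way ANOVA: ", aov2$table$term[i]),
          statistic = aov2$table$F[i],
          df = sprintf("%d,%d", aov2$table$df[i], aov2$table$df[4L]),
          p = aov2$table$p[i], correction = "none",
          stringsAsFactors = FALSE)
      }
      ph <- posthoc_pairwise(fits, group = "condition", method = "fdr",
                             q = config$fdr_q)
      for (i in seq_len(nrow(ph))) {
        rows[[length(rows) + 1L]] <- data.frame(
          test = sprintf("post-hoc t: %s vs %s Hz", ph$group_a[i],
                         ph$group_b[i]),
          statistic = ph$statistic[i], df = "", p = ph$p_adj[i],
          correction = "BH", stringsAsFactors = FALSE)
      }
      adj <- config$positions$id[config$positions$is_adjacent_to_disc]
      groups <- lapply(split(fits, fits$condition), function(d) {
        ref <- d$preferred_phase[d$position_id == adj]
        names(ref) <- d$subject[d$position_id == adj]
        oth <- d[d$position_id != adj, ]
        wrap_phase(oth$preferred_phase - ref[oth$subject])
      })
      ww <- watson_williams(groups)
      rows[[length(rows) + 1L]] <- data.frame(
        test = "Watson-Williams: adjacent-vs-distant phase shift across frequencies",
        statistic = ww$statistic,
        df = sprintf("%d,%d", ww$df1, ww$df2), p = ww$p_value,
        correction = "none", stringsAsFactors = FALSE)
    }
    cmp <- if (length(rows)) do.call(rbind, rows) else
      data.frame(test = character(0), statistic = numeric(0),
                 df = character(0), p = numeric(0),
                 correction = character(0))
    path <- file.path(outdir, "comparisons.tsv")
    utils::write.table(cmp, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    outputs <- c(outputs, path)
    timing$compare <- proc.time()[["elapsed"]] - t0
  }

  if ("report" %in% stages) {
    t0 <- proc.time()[["elapsed"]]
    write_report(outdir, freqs, freq_label)
    outputs <- c(outputs, file.path(outdir, "report.txt"))
    timing$report <- proc.time()[["elapsed"]] - t0
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("behavosc")),
    config_path = normalizePath(config_path),
    config = list(
      entrainment_frequencies = freqs,
      trial_duration = config$trial_duration,
      edge_margin = config$edge_margin,
      min_gap = config$min_gap,
      n_phase_bins = config$binning$n_bins,
      n_surrogates = n_surrogates,
      fdr_q = config$fdr_q,
      positions = config$positions,
      n_subjects = run$n_subjects,
      targets_per_cell = run$targets_per_cell
    ),
    seeds = c(list(run = run$seed), as.list(stage_seeds[stages[stages != "report"]])),
    outputs = outputs,
    timing_s = timing
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(manifest = manifest, outputs = outputs))
}

# assemble the plain-text report from the tables already on disk
write_report <- function(outdir, freqs, freq_label) {
  con <- file(file.path(outdir, "report.txt"), "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("behavosc pipeline report")
  w("========================")
  rd <- function(name) {
    p <- file.path(outdir, name)
    if (file.exists(p)) utils::read.delim(p, stringsAsFactors = FALSE) else NULL
  }
  amps <- rd("amplitude_tests.tsv")
  if (!is.null(amps)) {
    w("")
    w("Oscillatory amplitude of detection performance (group fixed-effect)")
    for (i in seq_len(nrow(amps))) {
      w("  %5s Hz  %-4s  peak-to-trough %5.1f%%  phase %+6.3f rad  p = %-8.4g %s",
        format(amps$condition[i]), amps$position_id[i],
        100 * amps$peak_to_trough[i], amps$preferred_phase[i],
        amps$p_raw[i], ifelse(amps$significant[i], "(FDR sig.)", ""))
    }
  }
  phd <- rd("phase_differences.tsv")
  if (!is.null(phd)) {
    w("")
    w("Preferred-phase differences between positions")
    for (i in seq_len(nrow(phd))) {
      if (is.na(phd$p_raw[i])) next
      w("  %5s Hz  %-3s vs %-3s  |dphi| = %5.3f rad  p = %-8.4g %s",
        format(phd$condition[i]), phd$position_a[i], phd$position_b[i],
        phd$phase_difference[i], phd$p_raw[i],
        ifelse(phd$significant[i], "(FDR sig.)", ""))
    }
  }
  for (nm in c("soa_control.tsv", "luminance_control.tsv")) {
    tb <- rd(nm)
    if (is.null(tb)) next
    w("")
    w("%s", if (nm == "soa_control.tsv") {
      "SOA masking control (single max-luminance flash)"
    } else {
      "Luminance-flash control (emulated phase cycle)"
    })
    for (i in seq_len(nrow(tb))) {
      w("  %-4s  peak-to-trough %5.1f%%  p = %-8.4g %s",
        tb$position_id[i], 100 * tb$peak_to_trough[i], tb$p_raw[i],
        ifelse(tb$significant[i], "(FDR sig.)", ""))
    }
  }
  cmp <- rd("comparisons.tsv")
  if (!is.null(cmp) && nrow(cmp)) {
    w("")
    w("Cross-condition comparisons")
    for (i in seq_len(nrow(cmp))) {
      w("  %-64s  stat %8.4g  p = %.4g", cmp$test[i], cmp$statistic[i],
        cmp$p[i])
    }
  }
  invisible(NULL)
}
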