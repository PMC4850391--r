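#' Write target-event tables to delimited text
#'
#' Serialises the target events of one or more subject datasets to a single
#' tab-separated table (columns: `subject`, `trial`, `position_id`,
#' `onset_s`, `luminance`, `phase_rad`, `bin`, `detected`; angles in radians,
#' times in seconds) plus a JSON metadata sidecar (`<path>.meta.json`)
#' recording the timing constants and per-subject entrainment frequency
#' needed to validate the table on read.
#'
#' @param datasets List of `subject_dataset` objects (or a single one).
#' @param path Output file path for the table.
#' @param config The [experiment_config()] the data were generated under.
#' @return `path`, invisibly.
#' @export
write_targets <- function(datasets, path, config) {
  if (inherits(datasets, "subject_dataset")) datasets <- list(datasets)
  stopifnot(all(vapply(datasets, inherits, TRUE, "subject_dataset")),
            inherits(config, "experiment_config"))
  tab <- do.call(rbind, lapply(datasets, `[[`, "targets"))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta <- list(
    schema = "behavosc targets v1 (onset_s seconds, phase_rad radians in [-pi, pi))",
    trial_duration = config$trial_duration,
    edge_margin = config$edge_margin,
    min_gap = config$min_gap,
    n_phase_bins = config$binning$n_bins,
    subjects = lapply(datasets, function(d) {
      list(subject = d$subject,
           entrainment_frequency = d$entrainment_frequency,
           n_trials = d$n_trials)
    })
  )
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Read a target-event table back into subject datasets
#'
#' Reads a table written by [write_targets()] and re-validates every
#' invariant: schema, onset times inside the trial margins, minimum gaps
#' between consecutive targets within a trial, detection flags, and the
#' consistency of the stored phase bin with [assign_phase_bin()] applied to
#' the stored phase. Violations abort with the offending row numbers.
#'
#' @param path Path to the table.
#' @param config The [experiment_config()] describing the design; defaults
#'   to the timing constants recorded in the metadata sidecar.
#' @return A list of `subject_dataset` objects (staircase traces are not
#'   serialised and come back as `NULL`). An empty table yields an empty
#'   list with a warning.
#' @export
read_targets <- function(path, config = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  schema <- c("subject", "trial", "position_id", "onset_s", "luminance",
              "phase_rad", "bin", "detected")
  if (!identical(sort(names(tab)), sort(schema))) {
    stop("schema mismatch: expected columns ",
         paste(schema, collapse = ", "), call. = FALSE)
  }
  tab <- tab[, schema]
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else NULL
  if (is.null(config)) {
    if (is.null(meta)) {
      stop("no config given and no metadata sidecar found next to ", path,
           call. = FALSE)
    }
    config <- experiment_config(
      entrainment_frequency = meta$subjects[[1L]]$entrainment_frequency,
      trial_duration = meta$trial_duration,
      edge_margin = meta$edge_margin,
      min_gap = meta$min_gap,
      n_phase_bins = meta$n_phase_bins
    )
  }
  if (nrow(tab) == 0L) {
    warning("empty target table: ", path, call. = FALSE)
    return(list())
  }
  tab$detected <- as.logical(tab$detected)
  bad <- function(rows, what) {
    stop(sprintf("invalid target table %s: %s at row(s) %s", path, what,
                 paste(utils::head(rows, 10L), collapse = ", ")),
         call. = FALSE)
  }
  if (anyNA(tab$detected)) bad(which(is.na(tab$detected)), "bad detected flag")
  lo <- config$edge_margin - 1e-9
  hi <- config$trial_duration - config$edge_margin + 1e-9
  off <- which(tab$onset_s < lo | tab$onset_s > hi)
  if (length(off)) bad(off, "onset outside trial margins")
  bin_chk <- assign_phase_bin(tab$phase_rad, config$binning)
  mismatch <- which(bin_chk != tab$bin)
  if (length(mismatch)) bad(mismatch, "phase bin inconsistent with phase")
  # per-trial minimum gap
  key <- paste(tab$subject, tab$trial)
  for (k in unique(key[duplicated(key)])) {
    rows <- which(key == k)
    d <- diff(sort(tab$onset_s[rows]))
    if (any(d < config$min_gap - 1e-9)) {
      bad(rows, sprintf("targets closer than the %.3g s minimum gap",
                        config$min_gap))
    }
  }
  freq_of <- function(subj) {
    if (is.null(meta)) return(config$entrainment_frequency)
    for (s in meta$subjects) {
      if (identical(s$subject, subj)) return(s$entrainment_frequency)
    }
    config$entrainment_frequency
  }
  lapply(split(tab, tab$subject), function(d) {
    rownames(d) <- NULL
    structure(
      list(subject = d$subject[1L],
           entrainment_frequency = freq_of(d$subject[1L]),
           n_trials = length(unique(d$trial)),
           targets = d,
           staircase_trace = NULL),
      class = "subject_dataset")
  })
}

#' Read a run configuration file
#'
#' Parses a YAML run configuration with three blocks — `experiment`
#' (fields of [experiment_config()], plus `layout: exp1|exp2`), `observer`
#' (fields of [observer_model()]) and `run` (`n_subjects`,
#' `targets_per_cell`, `seed`, optional `frequencies` vector to simulate
#' several entrainment conditions, optional `staircase_step`,
#' `start_luminance`) — into the corresponding objects.
#'
#' @param path Path to the YAML file.
#' @return A list with elements `config`, `observer` and `run`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  for (block in c("experiment", "observer", "run")) {
    if (is.null(raw[[block]])) {
      stop(sprintf("config error: missing block '%s'", block), call. = FALSE)
    }
  }
  ex <- raw$experiment
  layout <- ex$layout %||% "exp2"
  positions <- switch(layout,
    exp1 = positions_exp1(),
    exp2 = positions_exp2(),
    stop(sprintf("config error: unknown layout '%s' (key experiment.layout)",
                 layout), call. = FALSE))
  cfg_args <- ex[setdiff(names(ex), "layout")]
  allowed <- setdiff(names(formals(experiment_config)), "positions")
  unknown <- setdiff(names(cfg_args), allowed)
  if (length(unknown)) {
    stop("config error: unknown experiment key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (!is.null(cfg_args$target_count_probs)) {
    cfg_args$target_count_probs <- unlist(cfg_args$target_count_probs)
  }
  config <- do.call(experiment_config, c(cfg_args, list(positions = positions)))

  ob <- raw$observer
  allowed_ob <- setdiff(names(formals(observer_model)), "positions")
  unknown <- setdiff(names(ob), allowed_ob)
  if (length(unknown)) {
    stop("config error: unknown observer key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  ob <- lapply(ob, function(x) if (is.list(x)) unlist(x) else x)
  observer <- do.call(observer_model, c(ob, list(positions = positions)))

  run <- raw$run
  run$n_subjects <- as.integer(run$n_subjects %||% 3L)
  run$targets_per_cell <- run$targets_per_cell %||% 33
  run$seed <- run$seed %||% 1L
  run$frequencies <- unlist(run$frequencies %||% config$entrainment_frequency)
  run$staircase_step <- run$staircase_step %||% 1.1
  run$start_luminance <- run$start_luminance %||% 150

  list(config = config, observer = observer, run = run)
}
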