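# Dataset container, run configuration and the command-line surface.

CONTAINER_VERSION <- 1L

write_num_tsv <- function(M, path, col_names) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(col_names, collapse = "\t"), con)
  apply_fmt <- function(row) paste(sprintf("%.17g", row), collapse = "\t")
  writeLines(vapply(seq_len(nrow(M)), function(i) apply_fmt(M[i, ]), ""), con)
}

read_num_tsv <- function(path) {
  M <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                                   check.names = FALSE))
  storage.mode(M) <- "double"
  M
}

#' Export a schedule as a plain event table
#'
#' Writes (or returns) a tab-separated table with columns `onset_s`,
#' `duration_s`, `label`, one row per task period.
#'
#' @param x a [make_schedule()] result or a `bci_dataset`.
#' @param path optional output file; when `NULL` the data.frame is returned.
#' @return the event data.frame, invisibly when written.
#' @export
export_events <- function(x, path = NULL) {
  tabs <- if (inherits(x, "bci_dataset"))
    lapply(x$sessions, function(s) export_events(s$schedule))
  else if (inherits(x, "paradigm_schedule"))
    list(data.frame(onset_s = x$trials$task_onset_s,
                    duration_s = x$trials$task_len_s,
                    label = x$trials$label,
                    session = x$session_id))
  else stop_hbci("cannot export events from this object", "hbci_config_error")
  ev <- do.call(rbind, tabs)
  if (!is.null(path)) {
    utils::write.table(ev, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(ev))
  }
  ev
}

rec_to_files <- function(rec, stem, dir) {
  fn <- paste0(stem, ".tsv")
  write_num_tsv(t(rec$data), file.path(dir, fn), rec$channel_labels)
  list(file = fn, modality = rec$modality, fs = rec$fs, units = rec$units,
       channels = rec$channel_labels,
       marker_sample = rec$markers$sample_index,
       marker_label = rec$markers$label)
}

rec_from_files <- function(meta, dir) {
  M <- read_num_tsv(file.path(dir, meta$file))
  continuous_recording(meta$modality, meta$fs, t(M), meta$channels,
                       meta$units,
                       data.frame(sample_index = as.integer(meta$marker_sample),
                                  label = as.character(meta$marker_label)))
}

#' Write a dataset container
#'
#' Serializes a [simulate_dataset()] result into a directory of plain
#' tab-separated numeric arrays plus a versioned JSON manifest carrying
#' rates, units, channel labels, markers, schedules and per-file MD5
#' checksums. `read_container(write_container(x))` is bit-exact.
#'
#' @param dataset a `bci_dataset`.
#' @param path target directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_container <- function(dataset, path) {
  stopifnot(inherits(dataset, "bci_dataset"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  sessions <- list()
  for (i in seq_along(dataset$sessions)) {
    s <- dataset$sessions[[i]]
    stem <- sprintf("session%02d", s$schedule$session_id)
    sessions[[i]] <- list(
      session_id = s$schedule$session_id,
      pre_rest_s = s$schedule$pre_rest_s,
      post_rest_s = s$schedule$post_rest_s,
      total_len_s = s$schedule$total_len_s,
      trials = s$schedule$trials,
      eeg = rec_to_files(s$eeg, paste0(stem, "_eeg"), path),
      eog = rec_to_files(s$eog, paste0(stem, "_eog"), path),
      nirs = rec_to_files(s$nirs, paste0(stem, "_nirs"), path))
  }
  manifest <- list(format_version = CONTAINER_VERSION,
                   n_sessions = length(sessions), sessions = sessions)
  files <- list.files(path, pattern = "\\.tsv$")
  manifest$checksums <- as.list(tools::md5sum(file.path(path, files)))
  names(manifest$checksums) <- files
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "columns")
  invisible(path)
}

#' Read a dataset container
#'
#' Validates the manifest version and per-file checksums, then reconstructs
#' the recordings and schedules bit-exactly.
#'
#' @param path container directory written by [write_container()].
#' @return a `bci_dataset` (without the generating `sim_config`).
#' @export
read_container <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf))
    stop_hbci("no manifest.json: run the simulate command first",
              "hbci_missing_artifact")
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE,
                                  simplifyDataFrame = FALSE)
  if (!identical(as.integer(manifest$format_version), CONTAINER_VERSION))
    stop_hbci(sprintf("unsupported container version %s (expected %d)",
                      manifest$format_version, CONTAINER_VERSION),
              "hbci_version_error")
  for (fn in names(manifest$checksums)) {
    got <- unname(tools::md5sum(file.path(path, fn)))
    if (!identical(got, manifest$checksums[[fn]]))
      stop_hbci(sprintf("checksum mismatch for %s: container is corrupt", fn),
                "hbci_corruption_error")
  }
  sessions <- lapply(manifest$sessions, function(s) {
    trials <- as.data.frame(lapply(s$trials, unlist),
                            stringsAsFactors = FALSE)
    sched <- structure(list(session_id = as.integer(s$session_id),
                            pre_rest_s = s$pre_rest_s,
                            post_rest_s = s$post_rest_s,
                            total_len_s = s$total_len_s, trials = trials),
                       class = "paradigm_schedule")
    list(schedule = sched, eeg = rec_from_files(s$eeg, path),
         eog = rec_from_files(s$eog, path),
         nirs = rec_from_files(s$nirs, path))
  })
  structure(list(config = NULL, sessions = sessions), class = "bci_dataset")
}

default_run_config <- function() list(
  seed = 1L,
  simulation = list(n_sessions = 3L, fs_eeg = 200, fs_nirs = 12.5,
                    n_trials_per_class = 10L, pre_rest_s = 60,
                    post_rest_s = 60, session_drift_sd = 0.15,
                    emit_optical_density = FALSE),
  preprocessing = list(eog_method = "regression", eeg_band = c(1, 40),
                       eeg_order = 4, nirs_band = c(0.01, 0.2),
                       nirs_order = 6, target_fs = 100,
                       window = c(-5, 5), baseline = c(-5, -2)),
  features = list(csp_pairs = 3, slope_method = "lsfit"),
  classification = list(inner_folds = 5, target = "scaled_identity"),
  evaluation = list(repetitions = 10, folds = 5,
                    pseudo_online_mode = "causal", trial_len_s = 5,
                    alpha = 0.05, pairs = list(c("MA", "BL"), c("WC", "BL"))))

merge_config <- function(base, override, path = "") {
  for (k in names(override)) {
    if (!k %in% names(base))
      stop_hbci(sprintf("unknown configuration key '%s%s'", path, k),
                "hbci_config_error")
    # named lists are sections to merge recursively; unnamed lists (e.g. the
    # class-pair list) are plain values
    base[[k]] <- if (is.list(base[[k]]) && is.list(override[[k]]) &&
                     !is.null(names(base[[k]])))
      merge_config(base[[k]], override[[k]], paste0(path, k, "."))
    else override[[k]]
  }
  base
}

#' Load and validate a run configuration
#'
#' Reads a YAML file (or takes a list), fills unspecified values with the
#' defaults and rejects unknown keys.
#'
#' @param x path to a YAML file, a list of overrides, or `NULL` for the
#'   defaults.
#' @return a validated `run_config` list.
#' @export
run_config <- function(x = NULL) {
  override <- if (is.null(x)) list()
  else if (is.character(x)) yaml::read_yaml(x)
  else if (is.list(x)) x
  else stop_hbci("config must be a path or a list", "hbci_config_error")
  cfg <- merge_config(default_run_config(), override)
  class(cfg) <- c("run_config", "list")
  cfg
}

run_sim_config <- function(cfg) {
  s <- cfg$simulation
  sim_config(seed = cfg$seed, n_sessions = s$n_sessions, fs_eeg = s$fs_eeg,
             fs_nirs = s$fs_nirs, n_trials_per_class = s$n_trials_per_class,
             pre_rest_s = s$pre_rest_s, post_rest_s = s$post_rest_s,
             session_drift_sd = s$session_drift_sd,
             emit_optical_density = s$emit_optical_density)
}

run_preprocess <- function(cfg, dataset) {
  p <- cfg$preprocessing
  preprocess_dataset(dataset, eog_method = p$eog_method, eeg_band = p$eeg_band,
                     eeg_order = p$eeg_order, nirs_band = p$nirs_band,
                     nirs_order = p$nirs_order, target_fs = p$target_fs,
                     window = p$window, baseline = p$baseline)
}

#' Run the full pipeline in memory
#'
#' Simulate (or take) a dataset, preprocess it, and evaluate every class pair
#' of the configuration offline and pseudo-online, reporting accuracies and
#' information transfer rates.
#'
#' @param cfg a [run_config()] (or anything it accepts).
#' @param dataset optional existing `bci_dataset`; simulated from the config
#'   when `NULL`.
#' @param modalities modalities to evaluate.
#' @param mode `"both"` (default), `"offline"` or `"pseudo-online"`.
#' @return a `run_report` list: config echo, per-pair offline/pseudo-online
#'   summaries and ITRs.
#' @export
run_pipeline <- function(cfg = run_config(), dataset = NULL,
                         modalities = MODALITIES, mode = "both") {
  cfg <- run_config(if (inherits(cfg, "run_config")) unclass(cfg) else cfg)
  if (is.null(dataset)) dataset <- simulate_dataset(run_sim_config(cfg))
  trials <- run_preprocess(cfg, dataset)
  spec <- feature_spec(csp_pairs = cfg$features$csp_pairs,
                       slope_method = cfg$features$slope_method)
  ev <- cfg$evaluation
  pairs_out <- list()
  for (pair in ev$pairs) {
    key <- paste(pair, collapse = "_vs_")
    res <- list(chance_level = chance_level(sum(trials$eeg$labels %in% pair),
                                            ev$alpha))
    if (mode != "pseudo-online") {
      off <- crossvalidate_offline(trials, pair, spec,
                                   repetitions = ev$repetitions,
                                   folds = ev$folds, seed = cfg$seed,
                                   inner_folds = cfg$classification$inner_folds,
                                   modalities = modalities)
      off_sum <- summary(off)
      res$offline <- off_sum
      res$itr_offline_bits_per_min <- stats::setNames(
        itr(pmax(off_sum$mean_accuracy, 1e-12), N = 2,
            trial_len_s = ev$trial_len_s)$bits_per_min, off_sum$modality)
    }
    if (mode != "offline") {
      ps <- pseudo_online(trials, pair, mode = ev$pseudo_online_mode,
                          spec = spec,
                          inner_folds = cfg$classification$inner_folds,
                          modalities = modalities)
      ps_sum <- summary(ps)
      res$pseudo_online <- ps_sum
      res$itr_pseudo_online_bits_per_min <- stats::setNames(
        itr(pmax(ps_sum$mean_accuracy, 1e-12), N = 2,
            trial_len_s = ev$trial_len_s)$bits_per_min, ps_sum$modality)
    }
    pairs_out[[key]] <- res
  }
  structure(list(config = unclass(cfg), seed = cfg$seed, pairs = pairs_out),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  for (key in names(x$pairs)) {
    p <- x$pairs[[key]]
    cat(sprintf("  %s (chance %.3f):\n", key, p$chance_level))
    tab <- p$offline %||% p$pseudo_online
    for (i in seq_len(nrow(tab))) {
      line <- sprintf("    %-5s", tab$modality[i])
      if (!is.null(p$offline))
        line <- paste0(line, sprintf(" offline %.3f +/- %.3f | ITR %.2f bits/min",
                                     p$offline$mean_accuracy[i], p$offline$sd[i],
                                     p$itr_offline_bits_per_min[i]))
      if (!is.null(p$pseudo_online))
        line <- paste0(line, sprintf(" | pseudo-online %.3f",
                                     p$pseudo_online$mean_accuracy[i]))
      cat(line, "\n")
    }
  }
  invisible(x)
}

write_report <- function(report, path) {
  out <- list(seed = report$seed, config = report$config, pairs = list())
  for (key in names(report$pairs)) {
    p <- report$pairs[[key]]
    entry <- list(chance_level = p$chance_level)
    if (!is.null(p$offline)) {
      entry$offline <- p$offline
      entry$itr_offline_bits_per_min <- as.list(p$itr_offline_bits_per_min)
    }
    if (!is.null(p$pseudo_online)) {
      entry$pseudo_online <- p$pseudo_online
      entry$itr_pseudo_online_bits_per_min <-
        as.list(p$itr_pseudo_online_bits_per_min)
    }
    out$pairs[[key]] <- entry
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}

cli_usage <- function() {
  paste(
    "usage: hbci <command> [--config FILE] [--out DIR] [--seed N]",
    "            [--mode offline|pseudo-online|both] [--pair MA-BL|WC-BL]",
    "            [--eog none|regression|ica]",
    "commands: simulate    generate a synthetic dataset container",
    "          preprocess  epoch and clean a simulated container",
    "          features    export feature tables from preprocessed epochs",
    "          evaluate    offline + pseudo-online evaluation and ITR report",
    "          report      print a previously computed report",
    sep = "\n")
}

parse_cli_args <- function(args) {
  if (length(args) == 0) return(list(command = NULL))
  opts <- list(command = args[[1]], config = NULL, out = ".", seed = NULL,
               mode = "both", pair = NULL, eog = NULL)
  i <- 2L
  while (i <= length(args)) {
    key <- sub("^--", "", args[[i]])
    if (!key %in% c("config", "out", "seed", "mode", "pair", "eog") ||
        i == length(args))
      stop_hbci(sprintf("unknown or incomplete option '%s'", args[[i]]),
                "hbci_cli_error")
    opts[[key]] <- args[[i + 1L]]
    i <- i + 2L
  }
  opts
}

#' Command-line entry point
#'
#' Thin shell over the package functions; see `inst/cli/hbci` for the
#' executable wrapper. Each command reads the previous stage's artifacts from
#' the output directory and writes its own; all randomness flows from the
#' configured (or `--seed`) master seed.
#'
#' @param args character vector of command-line arguments.
#' @return exit status (0 on success), invisibly.
#' @export
bci_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    opts <- parse_cli_args(args)
    if (is.null(opts$command) ||
        !opts$command %in% c("simulate", "preprocess", "features",
                             "evaluate", "report")) {
      message(cli_usage())
      return(invisible(if (is.null(opts$command)) 0L else 1L))
    }
    cfg <- run_config(opts$config)
    if (!is.null(opts$seed)) cfg$seed <- as.integer(opts$seed)
    if (!is.null(opts$eog)) cfg$preprocessing$eog_method <- opts$eog
    if (!is.null(opts$pair))
      cfg$evaluation$pairs <- list(strsplit(opts$pair, "-")[[1]])
    out <- opts$out
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    raw_dir <- file.path(out, "raw")
    log <- function(...) message(sprintf("[hbci %s] ", opts$command),
                                 sprintf(...))
    t0 <- Sys.time()
    if (opts$command == "simulate") {
      ds <- simulate_dataset(run_sim_config(cfg))
      write_container(ds, raw_dir)
      export_events(ds, file.path(out, "events.tsv"))
      log("seed %d: wrote %d sessions to %s", cfg$seed, length(ds$sessions),
          raw_dir)
    } else if (opts$command %in% c("preprocess", "features", "evaluate")) {
      if (!dir.exists(raw_dir))
        stop_hbci("no raw dataset found: run 'simulate' first",
                  "hbci_missing_artifact")
      ds <- read_container(raw_dir)
      if (opts$command == "preprocess") {
        trials <- run_preprocess(cfg, ds)
        saveRDS(trials, file.path(out, "epochs.rds"))
        log("wrote epochs.rds (%d trials)", dim(trials$eeg$data)[1])
      } else if (opts$command == "features") {
        trials <- run_preprocess(cfg, ds)
        spec <- feature_spec(csp_pairs = cfg$features$csp_pairs,
                             slope_method = cfg$features$slope_method)
        nf <- nirs_features(trials$hbo, trials$hbr, spec)
        for (nm in names(nf)) {
          tab <- data.frame(nf[[nm]]$values, label = nf[[nm]]$labels,
                            session = nf[[nm]]$session_ids,
                            check.names = FALSE)
          utils::write.table(tab, file.path(out, paste0("features_", nm, ".tsv")),
                             sep = "\t", quote = FALSE, row.names = FALSE)
        }
        log("wrote NIRS feature tables (EEG features are fold-dependent)")
      } else {
        if (opts$mode %in% c("pseudo-online", "both") &&
            length(ds$sessions) < 2)
          stop_hbci("pseudo-online evaluation requires >= 2 sessions",
                    "hbci_config_error")
        report <- run_pipeline(cfg, dataset = ds, mode = opts$mode)
        write_report(report, file.path(out, "report.json"))
        print(report)
        log("wrote report.json")
      }
    } else if (opts$command == "report") {
      f <- file.path(out, "report.json")
      if (!file.exists(f))
        stop_hbci("no report.json found: run 'evaluate' first",
                  "hbci_missing_artifact")
      cat(readLines(f), sep = "\n")
    }
    log_line <- sprintf("%s | %s | seed %s | %.2f s", format(t0),
                        opts$command, cfg$seed,
                        as.numeric(difftime(Sys.time(), t0, units = "secs")))
    cat(log_line, "\n", file = file.path(out, "hbci.log"), append = TRUE)
    0L
  }, error = function(e) {
    message("hbci error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
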