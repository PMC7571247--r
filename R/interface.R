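#' Sweep run configuration
#'
#' Validated, JSON-serialisable description of a full sweep run: which
#' families and metrics to evaluate, the noise schedule and noise options,
#' the intensity-adjust policy, the input bank (synthetic counts or file
#' paths), the master seed and the output directory.
#'
#' @param families Wavelet families to sweep.
#' @param metrics Metrics to record, see [metric_names()].
#' @param schedule_kind `"schedule_1d"` or `"schedule_2d"`.
#' @param schedule_levels Optional explicit eta levels overriding the
#'   canonical schedule.
#' @param n_images,n_signals,image_size,signal_length,bank_seed Synthetic
#'   bank description (used when `input_paths` is empty).
#' @param input_paths Optional character vector of record files to load
#'   instead of generating a synthetic bank.
#' @param K,N Grid extents (decomposition levels and wavelet orders).
#' @param threshold_rule Shrinkage rule.
#' @param adjust Apply the recommended intensity adjustment to denoised
#'   images before scoring (default `FALSE`: identity window).
#' @param impulse_p,speckle_variance,gaussian_variance,gaussian_interpret
#'   Noise options, see the noise-model functions.
#' @param master_seed Master seed for noise draws.
#' @param output_dir Directory receiving tensors, summaries and logs.
#' @return A validated `run_config` object.
#' @export
run_config <- function(families = wavelet_families(),
                       metrics = c("corr", "mse", "ed"),
                       schedule_kind = "schedule_2d",
                       schedule_levels = NULL,
                       n_images = 2, n_signals = 0,
                       image_size = 64, signal_length = 1024,
                       bank_seed = 17, input_paths = character(),
                       K = 5, N = 5,
                       threshold_rule = "universal_soft",
                       adjust = FALSE,
                       impulse_p = 0.05, speckle_variance = 0.05,
                       gaussian_variance = 0.01, gaussian_interpret = "mean",
                       master_seed = 1, output_dir = "wavemap_run") {
  cfg <- list(families = vapply(families, normalize_family, ""),
              metrics = vapply(metrics, function(m) match.arg(m, metric_names()), ""),
              schedule_kind = match.arg(schedule_kind,
                                        c("schedule_1d", "schedule_2d")),
              schedule_levels = schedule_levels,
              n_images = n_images, n_signals = n_signals,
              image_size = image_size, signal_length = signal_length,
              bank_seed = bank_seed, input_paths = input_paths,
              K = K, N = N,
              threshold_rule = match.arg(threshold_rule,
                                         c("universal_soft", "universal_hard")),
              adjust = isTRUE(adjust),
              impulse_p = impulse_p, speckle_variance = speckle_variance,
              gaussian_variance = gaussian_variance,
              gaussian_interpret = match.arg(gaussian_interpret,
                                             c("mean", "variance")),
              master_seed = master_seed, output_dir = output_dir)
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

validate_run_config <- function(cfg) {
  # fail before any computation: every module invariant checked up front
  for (fam in cfg$families) for (n in seq_len(cfg$N)) filter_bank(fam, n)
  if (!is.null(cfg$schedule_levels)) noise_schedule(cfg$schedule_levels, cfg$schedule_kind)
  if (cfg$impulse_p <= 0 || cfg$impulse_p > 1) stop("impulse_p must lie in (0, 1]")
  if (cfg$speckle_variance < 0) stop("speckle_variance must be >= 0")
  if (cfg$gaussian_variance < 0) stop("gaussian_variance must be >= 0")
  if (cfg$K < 1 || cfg$N < 1) stop("grid extents K, N must be >= 1")
  if (length(cfg$input_paths) == 0 && cfg$n_images + cfg$n_signals < 1) {
    stop("configuration describes an empty bank")
  }
  invisible(TRUE)
}

config_schedule <- function(cfg) {
  if (!is.null(cfg$schedule_levels)) {
    noise_schedule(cfg$schedule_levels, cfg$schedule_kind)
  } else {
    default_schedule(cfg$schedule_kind)
  }
}

#' Read / write a run configuration as JSON
#'
#' @param path JSON file path.
#' @return `read_run_config` returns a validated `run_config`;
#'   `write_run_config` returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$input_paths <- as.character(raw$input_paths %||% character())
  do.call(run_config, raw[!vapply(raw, is.null, TRUE)])
}

#' @rdname read_run_config
#' @param config A `run_config`.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

config_bank <- function(config) {
  if (length(config$input_paths) > 0) {
    lapply(config$input_paths, load_record)
  } else {
    make_bank(config$n_images, config$n_signals, seed = config$bank_seed,
              image_size = config$image_size,
              signal_length = config$signal_length)
  }
}

# ---- tensor persistence ---------------------------------------------------

#' Save / load a volumetric response
#'
#' Tensors are persisted as a long-format CSV (`level`, `order`,
#' `eta_index`, `eta`, `item`, `value`; missing cells carried as empty
#' values) with a JSON sidecar holding the axis metadata (metric, family,
#' schedule, master seed, item labels).
#'
#' @param vr A `volumetric_response`.
#' @param path CSV output path; the sidecar is written next to it as
#'   `<path without .csv>_meta.json`.
#' @return `save_volumetric_response` returns `path` invisibly;
#'   `load_volumetric_response` returns the restored `volumetric_response`.
#' @export
save_volumetric_response <- function(vr, path) {
  stopifnot(inherits(vr, "volumetric_response"))
  d <- dim(vr$tensor)
  grid <- expand.grid(level = seq_len(d[1]), order = seq_len(d[2]),
                      eta_index = seq_len(d[3]), item = seq_len(d[4]))
  grid$eta <- vr$schedule$levels[grid$eta_index]
  grid$value <- as.numeric(vr$tensor)
  write.csv(grid[, c("level", "order", "eta_index", "eta", "item", "value")],
            path, row.names = FALSE)
  meta <- list(metric = vr$metric, family = vr$family,
               schedule_kind = vr$schedule$kind,
               schedule_levels = vr$schedule$levels,
               master_seed = vr$master_seed, item_ids = vr$item_ids,
               dims = d)
  jsonlite::write_json(meta, meta_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

meta_path <- function(path) paste0(sub("\\.csv$", "", path), "_meta.json")

#' @rdname save_volumetric_response
#' @export
load_volumetric_response <- function(path) {
  meta <- jsonlite::read_json(meta_path(path), simplifyVector = TRUE)
  df <- read.csv(path)
  d <- as.integer(meta$dims)
  ten <- array(NA_real_, d,
               dimnames = list(level = as.character(seq_len(d[1])),
                               order = as.character(seq_len(d[2])),
                               eta = as.character(meta$schedule_levels),
                               item = as.character(seq_len(d[4]))))
  ten[cbind(df$level, df$order, df$eta_index, df$item)] <- df$value
  structure(list(tensor = ten, metric = meta$metric, family = meta$family,
                 schedule = noise_schedule(meta$schedule_levels,
                                           meta$schedule_kind),
                 master_seed = meta$master_seed,
                 item_ids = as.character(meta$item_ids)),
            class = "volumetric_response")
}

#' Run a full parameter sweep from a configuration
#'
#' Builds (or loads) the input bank, sweeps every configured family over the
#' noise schedule computing all configured metrics, and persists:
#'
#' * one tensor CSV + JSON sidecar per (family, metric):
#'   `tensor_<family>_<metric>.csv`;
#' * `recommendations.csv` — best settings per (metric, noise level) across
#'   families;
#' * `family_summary.csv` — per-family mean achievable values and
#'   differences from the best family;
#' * `run_config.json` and `log.txt` (stage timings and seed provenance).
#'
#' Reruns from the same configuration are deterministic: the summary CSVs
#' are byte-identical.
#'
#' @param config A [run_config()] or path to its JSON form.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the bank, the per-family-per-metric
#'   volumetric responses, the recommendation tables and the family
#'   summaries.
#' @export
run_sweep <- function(config, quiet = TRUE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(sprintf("wavemap sweep: %d families, %d metrics, master_seed=%d",
                         length(config$families), length(config$metrics),
                         config$master_seed))
  t0 <- proc.time()[["elapsed"]]
  bank <- config_bank(config)
  schedule <- config_schedule(config)
  log_lines <- c(log_lines,
                 sprintf("bank: %d record(s); schedule: %d level(s) [%g..%g]",
                         length(bank), length(schedule$levels),
                         min(schedule$levels), max(schedule$levels)),
                 sprintf("bank ready after %.2fs", proc.time()[["elapsed"]] - t0))
  results <- list()
  for (fam in config$families) {
    t_fam <- proc.time()[["elapsed"]]
    vrs <- sweep_tensors(bank, fam, schedule, config$metrics,
                         config$master_seed,
                         K = config$K, N = config$N,
                         threshold_rule = config$threshold_rule,
                         adjust = config$adjust,
                         speckle_variance = config$speckle_variance,
                         impulse_p = config$impulse_p,
                         gaussian_variance = config$gaussian_variance,
                         gaussian_interpret = config$gaussian_interpret)
    for (m in config$metrics) {
      f <- file.path(config$output_dir, sprintf("tensor_%s_%s.csv", fam, m))
      save_volumetric_response(vrs[[m]], f)
    }
    results[[fam]] <- vrs
    log_lines <- c(log_lines, sprintf("family %s swept in %.2fs (seed base %d)",
                                      fam, proc.time()[["elapsed"]] - t_fam,
                                      config$master_seed))
    if (!quiet) message(log_lines[length(log_lines)])
  }
  recs <- NULL
  summaries <- NULL
  for (m in config$metrics) {
    per_fam <- lapply(results, function(vrs) vrs[[m]])
    rec <- best_settings(per_fam)
    rec_df <- as.data.frame(rec)
    rec_df$metric <- m
    recs <- rbind(recs, rec_df)
    summaries <- rbind(summaries, family_summary(per_fam))
  }
  write.csv(recs, file.path(config$output_dir, "recommendations.csv"),
            row.names = FALSE)
  write.csv(summaries, file.path(config$output_dir, "family_summary.csv"),
            row.names = FALSE)
  write_run_config(config, file.path(config$output_dir, "run_config.json"))
  log_lines <- c(log_lines, sprintf("total elapsed %.2fs",
                                    proc.time()[["elapsed"]] - t0))
  writeLines(log_lines, file.path(config$output_dir, "log.txt"))
  invisible(list(bank = bank, responses = results, recommendations = recs,
                 family_summaries = summaries, config = config))
}
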