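#' Run configuration
#'
#' Nested configuration for the analysis pipeline, optionally loaded from
#' a YAML or JSON file with blocks `impulse`, `saccade`, `gain`, `error`
#' and a `verbosity` level.  Unknown keys are rejected.
#'
#' @param path optional YAML/JSON config file.
#' @param ... named overrides, e.g. `saccade = list(max_saccades = 2)`.
#' @return list of class `vhit_config`.
#' @export
vhit_config <- function(path = NULL, ...) {
  defaults <- list(
    impulse = list(log_sigma_ms = 8, min_peak_velocity = 100,
                   max_peak_velocity = 300, max_duration_ms = 200),
    saccade = list(hp_cutoff_hz = 3, jerk_threshold = "auto",
                   max_saccades = 3, min_latency_ms = 50, max_iter = 500,
                   tol = 1e-6, log_sigma_ms = 8, min_peak_dps = 25),
    gain = list(window_pre_ms = 60, desaccade = TRUE),
    error = list(baseline_ms = 100),
    verbosity = 1)
  cfg <- defaults
  apply_block <- function(cfg, upd, where = "") {
    for (nm in names(upd)) {
      if (!nm %in% names(cfg))
        vorsac_stop("vorsac_config_error",
                    sprintf("unknown config key '%s%s'", where, nm))
      cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(upd[[nm]])) {
        apply_block(cfg[[nm]], upd[[nm]], paste0(where, nm, "."))
      } else upd[[nm]]
    }
    cfg
  }
  if (!is.null(path)) {
    if (!file.exists(path))
      vorsac_stop("vorsac_config_error", sprintf("config file not found: %s", path))
    parsed <- tryCatch(
      if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
      else yaml::read_yaml(path),
      error = function(e) vorsac_stop("vorsac_config_error",
                                      sprintf("cannot parse config %s: %s",
                                              path, conditionMessage(e))))
    cfg <- apply_block(cfg, parsed)
  }
  cfg <- apply_block(cfg, list(...))
  structure(cfg, class = "vhit_config")
}

cfg_impulse <- function(cfg) do.call(impulse_config, cfg$impulse)
cfg_fit <- function(cfg) do.call(fit_config, cfg$saccade)

#' Analyze one trace end to end
#'
#' Detects the impulse, fits and classifies saccades, computes the
#' position-ratio gain and the pre-saccadic visual position errors.
#' Per-trial rejections (no impulse, out-of-envelope stimulus, truncated
#' trace) are returned as a `trial_rejection` object rather than thrown.
#'
#' @param trace a `vhit_trace`.
#' @param config a [vhit_config()].
#' @return a `result_record`, or a `trial_rejection` (fields `trial_id`,
#'   `reason`, `message`).
#' @export
analyze_trace <- function(trace, config = vhit_config()) {
  tryCatch({
    imp <- detect_impulse(trace, cfg_impulse(config))
    fits <- fit_saccades(trace, imp, cfg_fit(config))
    gain <- compute_gain(trace, imp, fits,
                         desaccade = config$gain$desaccade,
                         window_pre_ms = config$gain$window_pre_ms)
    perr <- position_error_at_saccades(trace, imp, fits,
                                       baseline_ms = config$error$baseline_ms)
    result_record(trace, imp, gain, fits, perr)
  },
  vorsac_no_impulse = function(e) reject(trace, e),
  vorsac_rejected = function(e) reject(trace, e),
  vorsac_truncation_error = function(e) reject(trace, e),
  vorsac_unstable_denominator = function(e) reject(trace, e),
  vorsac_anchoring_error = function(e) reject(trace, e))
}

reject <- function(trace, e) {
  structure(list(trial_id = trace$trial_id,
                 reason = e$reason %||% class(e)[1],
                 message = conditionMessage(e)),
            class = "trial_rejection")
}

#' Analyze a batch of traces from disk
#'
#' Reads the trace CSV(s), analyzes every trial, writes `results.tsv` and
#' `summary.tsv` to the output directory, and logs one `key=value` line
#' per trial to stderr.  Per-trial rejections are logged, not fatal.
#'
#' @param input a trace CSV file, a directory of trace CSVs, or a list of
#'   `vhit_trace` objects.
#' @param out_dir output directory (created if needed); `NULL` skips
#'   writing.
#' @param config a [vhit_config()].
#' @return invisibly, list with `records`, `rejections`, `summary`,
#'   `n_accepted`, `n_rejected`, and output paths.
#' @export
vhit_analyze <- function(input, out_dir = NULL, config = vhit_config()) {
  traces <- if (is.list(input) && !is.character(input)) {
    input
  } else if (dir.exists(input)) {
    files <- list.files(input, pattern = "\\.csv$", full.names = TRUE)
    if (!length(files))
      vorsac_stop("vorsac_io_error", sprintf("no trace CSVs in %s", input))
    unlist(lapply(sort(files), read_traces), recursive = FALSE)
  } else {
    read_traces(input)
  }
  t0 <- proc.time()[["elapsed"]]
  out <- lapply(traces, function(tr) {
    res <- analyze_trace(tr, config)
    if (config$verbosity > 0) {
      if (inherits(res, "trial_rejection")) {
        message(sprintf("trial=%s status=rejected reason=%s", tr$trial_id,
                        res$reason))
      } else {
        message(sprintf("trial=%s status=ok saccades=%d gain=%.3f",
                        tr$trial_id, length(res$saccades), res$gain$gain))
      }
    }
    res
  })
  records <- Filter(function(x) inherits(x, "result_record"), out)
  rejections <- Filter(function(x) inherits(x, "trial_rejection"), out)
  summary <- summarize_records(records)
  paths <- list()
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths$results <- file.path(out_dir, "results.tsv")
    paths$summary <- file.path(out_dir, "summary.tsv")
    write_results(records, paths$results)
    write_summary(summary, paths$summary)
  }
  if (config$verbosity > 0)
    message(sprintf("analyzed=%d accepted=%d rejected=%d elapsed_s=%.2f",
                    length(out), length(records), length(rejections),
                    proc.time()[["elapsed"]] - t0))
  invisible(c(list(records = records, rejections = rejections,
                   summary = summary, n_accepted = length(records),
                   n_rejected = length(rejections)), paths))
}

#' Simulate a synthetic cohort to disk
#'
#' @param preset preset name (see [scenario_presets()]) or a
#'   [synth_config()].
#' @param n number of trials.
#' @param seed RNG seed (mandatory).
#' @param out_dir output directory; `traces.csv` and `truth.json` are
#'   written there.  `NULL` skips writing.
#' @return invisibly, list with `traces`, `truth`, and paths.
#' @export
vhit_simulate <- function(preset, n = 100, seed, out_dir = NULL) {
  cfg <- if (inherits(preset, "synth_config")) preset else scenario_presets(preset)
  cfg$n_trials <- n
  batch <- generate_batch(cfg, seed = seed)
  paths <- list()
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths$traces <- file.path(out_dir, "traces.csv")
    paths$truth <- file.path(out_dir, "truth.json")
    write_traces(batch$traces, paths$traces)
    jsonlite::write_json(batch$truth, paths$truth, auto_unbox = TRUE,
                         digits = NA, dataframe = "columns")
  }
  invisible(c(batch, paths))
}

#' Simulate-analyze-compare recovery harness
#'
#' Simulates a preset cohort, runs the full pipeline, and compares the
#' pipeline's estimates of VOR gain, first-saccade frequency, amplitude
#' and onset latency against both the generator's ground truth and the
#' preset's nominal parameters.
#'
#' @param preset preset name or `synth_config`.
#' @param n number of trials.
#' @param seed RNG seed.
#' @param config analysis [vhit_config()].
#' @return data.frame report with columns `metric`, `estimate`, `truth`
#'   (realized generator values), `nominal` (preset parameters),
#'   `tolerance`, `pass` (|estimate - truth| <= tolerance).
#' @export
vhit_recover <- function(preset, n = 100, seed, config = vhit_config()) {
  cfg <- if (inherits(preset, "synth_config")) preset else scenario_presets(preset)
  cfg$n_trials <- n
  batch <- generate_batch(cfg, seed = seed)
  old_v <- config$verbosity; config$verbosity <- 0
  res <- vhit_analyze(batch$traces, out_dir = NULL, config = config)
  config$verbosity <- old_v

  ok_ids <- vapply(res$records, `[[`, character(1), "trial_id")
  truth <- batch$truth[vapply(batch$truth, function(x)
    x$trial_id %in% ok_ids, logical(1))]

  est_gain <- mean(vapply(res$records, function(r) r$gain$gain, numeric(1)))
  true_gain <- mean(vapply(truth, `[[`, numeric(1), "gain"))

  first <- lapply(res$records, function(r)
    Filter(function(f) identical(f$seq_index, 1L), r$saccades))
  est_freq <- 100 * mean(lengths(first) > 0)
  true_freq <- 100 * mean(vapply(truth, function(x)
    nrow(x$saccades) > 0, logical(1)))

  f1 <- unlist(first, recursive = FALSE)
  est_amp <- mean(vapply(f1, function(f) abs(f$amplitude_deg), numeric(1)))
  est_lat <- mean(vapply(f1, `[[`, numeric(1), "onset_latency_ms"))
  t1 <- do.call(rbind, lapply(truth, function(x)
    x$saccades[x$saccades$index == 1, , drop = FALSE]))
  true_amp <- if (!is.null(t1) && nrow(t1)) mean(t1$amplitude_deg) else NA
  true_lat <- if (!is.null(t1) && nrow(t1)) mean(t1$latency_ms) else NA

  p1 <- if (length(cfg$saccades)) cfg$saccades[[1]]$probability * 100 else 0
  nom <- c(cfg$vor_gain[1], p1,
           if (length(cfg$saccades)) cfg$saccades[[1]]$amplitude[1] else NA,
           if (length(cfg$saccades)) cfg$saccades[[1]]$latency_ms[1] else NA)
  est <- c(est_gain, est_freq, est_amp, est_lat)
  tru <- c(true_gain, true_freq, true_amp, true_lat)
  tolr <- c(0.02, 3 * sqrt(max(p1 / 100 * (1 - p1 / 100), 0.002) / n) * 100,
            0.3, 8)
  data.frame(metric = c("vor_gain", "saccade1_frequency_pct",
                        "saccade1_amplitude_deg", "saccade1_latency_ms"),
             estimate = est, truth = tru, nominal = nom, tolerance = tolr,
             pass = is.finite(est) & is.finite(tru) & abs(est - tru) <= tolr)
}
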