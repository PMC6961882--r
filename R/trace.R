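#' @title vHIT trial containers and trace CSV input/output
#' @name trace-io
#' @description A `vhit_trace` holds one head-impulse trial: aligned head
#'   and eye angular velocity series plus canal/side/condition/group
#'   metadata.  Traces travel in a long-format CSV, one row per sample,
#'   metadata repeated per row.
NULL

.canals <- c("lateral", "anterior", "posterior")
.sides <- c("left", "right")
.conditions <- c("light", "dark")
.groups <- c("normal", "uvd_contra", "uvd_ipsi", "bvl", "bvd")

#' Construct and validate a vHIT trace
#'
#' @param trial_id character scalar identifying the trial.
#' @param t time vector in ms, uniformly sampled, strictly increasing.
#' @param v_head head angular velocity (deg/s), positive = rightward/upward
#'   rotation.
#' @param v_eye eye-in-head angular velocity (deg/s), same axis convention,
#'   so a perfectly compensatory VOR has `v_eye ~ -gain * v_head`.
#' @param fs nominal sampling rate in Hz (100-1000; vHIT goggles ~250).
#' @param canal semicircular-canal plane: "lateral", "anterior", "posterior".
#' @param side "left" or "right".
#' @param condition lighting: "light" (visual fixation) or "dark".
#' @param group subject group: "normal", "uvd_contra", "uvd_ipsi", "bvl",
#'   "bvd".
#' @return object of class `vhit_trace`.
#' @export
vhit_trace <- function(trial_id, t, v_head, v_eye, fs = 250,
                       canal = "lateral", side = "left",
                       condition = "light", group = "normal") {
  tr <- structure(
    list(trial_id = as.character(trial_id), t = as.numeric(t),
         v_head = as.numeric(v_head), v_eye = as.numeric(v_eye),
         fs = as.numeric(fs),
         canal = canal, side = side, condition = condition, group = group),
    class = "vhit_trace")
  validate_trace(tr)
  tr
}

#' Validate a vHIT trace
#'
#' Checks length agreement, finiteness, enum metadata, sampling-rate range
#' and time-base uniformity (spacing within 1% of `1/fs`).
#'
#' @param tr a `vhit_trace`.
#' @return `tr`, invisibly, or a classed validation/data error.
#' @export
validate_trace <- function(tr) {
  id <- tr$trial_id %||% "<unknown>"
  if (!is.numeric(tr$fs) || length(tr$fs) != 1 || tr$fs < 100 || tr$fs > 1000)
    vorsac_stop("vorsac_validation_error",
                sprintf("trial %s: fs must be in [100, 1000] Hz", id))
  n <- length(tr$t)
  if (n < 3 || length(tr$v_head) != n || length(tr$v_eye) != n)
    vorsac_stop("vorsac_validation_error",
                sprintf("trial %s: t, v_head, v_eye must share length >= 3", id))
  if (!all(is.finite(tr$t)) || !all(is.finite(tr$v_head)) ||
      !all(is.finite(tr$v_eye)))
    vorsac_stop("vorsac_validation_error",
                sprintf("trial %s: non-finite values in trace", id))
  dt <- diff(tr$t)
  nominal <- 1000 / tr$fs
  if (any(dt <= 0))
    vorsac_stop("vorsac_data_error",
                sprintf("trial %s: time vector not strictly increasing", id))
  if (any(abs(dt - nominal) > 0.01 * nominal))
    vorsac_stop("vorsac_data_error", sprintf(
      "trial %s: non-uniform sampling (spacing deviates > 1%% from 1/fs)", id))
  ok <- function(v, set) is.character(v) && length(v) == 1 && v %in% set
  if (!ok(tr$canal, .canals) || !ok(tr$side, .sides) ||
      !ok(tr$condition, .conditions) || !ok(tr$group, .groups))
    vorsac_stop("vorsac_validation_error", sprintf(
      "trial %s: unknown canal/side/condition/group metadata value", id))
  invisible(tr)
}

#' @export
print.vhit_trace <- function(x, ...) {
  cat(sprintf("vHIT trace '%s': %d samples @ %g Hz (%.0f ms)\n",
              x$trial_id, length(x$t), x$fs, diff(range(x$t))))
  cat(sprintf("  %s canal, %s side, %s, group %s\n",
              x$canal, x$side, x$condition, x$group))
  cat(sprintf("  peak |head| %.1f deg/s, peak |eye| %.1f deg/s\n",
              max(abs(x$v_head)), max(abs(x$v_eye))))
  invisible(x)
}

#' @export
plot.vhit_trace <- function(x, ...) {
  graphics::plot(x$t, x$v_head, type = "l", col = "black",
                 xlab = "time (ms)", ylab = "angular velocity (deg/s)",
                 main = sprintf("%s (%s %s, %s)", x$trial_id, x$side,
                                x$canal, x$condition), ...)
  graphics::lines(x$t, x$v_eye, col = "red3")
  graphics::abline(h = 0, lty = 3)
  graphics::legend("topright", c("head", "eye"), lty = 1,
                   col = c("black", "red3"), bty = "n")
  invisible(x)
}

.trace_cols <- c("trial_id", "group", "canal", "side", "condition", "fs",
                 "time_ms", "head_vel", "eye_vel")

#' Read vHIT traces from a long-format CSV
#'
#' Expects columns `trial_id, group, canal, side, condition, fs, time_ms,
#' head_vel, eye_vel`; rows are grouped by `trial_id` and ordered by time.
#'
#' @param path CSV file path.
#' @return list of `vhit_trace`, in order of first appearance.
#' @export
read_traces <- function(path) {
  if (!file.exists(path))
    vorsac_stop("vorsac_io_error", sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.trace_cols, names(df))
  if (length(missing))
    vorsac_stop("vorsac_format_error",
                sprintf("missing column(s): %s", paste(missing, collapse = ", ")))
  ids <- unique(df$trial_id)
  lapply(ids, function(id) {
    rows <- df[df$trial_id == id, , drop = FALSE]
    rows <- rows[order(rows$time_ms), , drop = FALSE]
    if (anyDuplicated(rows$time_ms))
      vorsac_stop("vorsac_data_error",
                  sprintf("trial %s: repeated timestamp", id))
    vhit_trace(id, rows$time_ms, rows$head_vel, rows$eye_vel,
               fs = rows$fs[1], canal = rows$canal[1], side = rows$side[1],
               condition = rows$condition[1], group = rows$group[1])
  })
}

#' Write vHIT traces to the long-format CSV dialect
#'
#' @param traces list of `vhit_trace` (or a single trace).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path) {
  if (inherits(traces, "vhit_trace")) traces <- list(traces)
  rows <- lapply(traces, function(tr) {
    data.frame(trial_id = tr$trial_id, group = tr$group, canal = tr$canal,
               side = tr$side, condition = tr$condition, fs = tr$fs,
               time_ms = tr$t, head_vel = tr$v_head, eye_vel = tr$v_eye,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  utils::write.csv(format_num_df(df), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Full-precision numeric formatting so write/read round-trips losslessly.
format_num_df <- function(df) {
  for (nm in names(df)) {
    if (is.numeric(df[[nm]])) df[[nm]] <- sprintf("%.17g", df[[nm]])
  }
  df
}
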