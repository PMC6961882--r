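#' Per-trial analysis record
#'
#' Bundles everything the pipeline produces for one accepted trial.
#' Saccades are stored sorted by onset latency; only post-50-ms saccades
#' survive classification, so every stored onset latency exceeds the
#' exclusion floor.
#'
#' @param trace the analyzed `vhit_trace` (metadata is copied).
#' @param impulse `impulse_segment`.
#' @param gain `gain_result`.
#' @param saccades list of classified `saccade_fit`.
#' @param position_errors data.frame from
#'   [position_error_at_saccades()].
#' @return object of class `result_record`.
#' @export
result_record <- function(trace, impulse, gain, saccades = list(),
                          position_errors = NULL) {
  lat <- vapply(saccades, `[[`, numeric(1), "onset_latency_ms")
  if (is.unsorted(lat)) saccades <- saccades[order(lat)]
  structure(list(trial_id = trace$trial_id, group = trace$group,
                 canal = trace$canal, side = trace$side,
                 condition = trace$condition, fs = trace$fs,
                 impulse = impulse, gain = gain, saccades = saccades,
                 position_errors = position_errors),
            class = "result_record")
}

.res_meta <- c("trial_id", "group", "canal", "side", "condition", "fs")
.res_imp <- c("onset_ms", "t_peak_acc_ms", "t_peak_vel_ms", "t_zero_cross_ms",
              "direction", "amplitude_deg", "peak_velocity_dps",
              "peak_acceleration_dps2", "duration_ms", "bounce_pct")
.res_gain <- c("gain", "window_start_ms", "window_end_ms", "eye_area_deg",
               "head_area_deg")
.res_sac <- c("A", "B", "t_peak_ms", "sigma_ms", "amplitude_deg",
              "peak_velocity_dps", "onset_ms", "onset_latency_ms",
              "seq_index", "timing_class", "direction_class", "J",
              "residual_rms", "converged", "n_iter")

#' Write analysis records to a flat results TSV
#'
#' One `impulse` row per trial (impulse and gain fields) plus one
#' `saccade` row per fitted saccade; numeric fields are written at full
#' precision so [read_results()] round-trips losslessly.
#'
#' @param records list of `result_record` (may be empty: header only).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(records, path) {
  rows <- lapply(records, function(rec) {
    meta <- as.data.frame(rec[.res_meta], stringsAsFactors = FALSE)
    imp <- cbind(meta, row_type = "impulse",
                 stats::setNames(as.data.frame(rec$impulse[.res_imp]),
                                 paste0("imp_", .res_imp)),
                 stats::setNames(as.data.frame(rec$gain[.res_gain]), .res_gain))
    sac <- lapply(seq_along(rec$saccades), function(i) {
      f <- rec$saccades[[i]]
      pe <- rec$position_errors
      err <- if (!is.null(pe) && i <= nrow(pe)) pe$error_deg[i] else NA_real_
      cbind(meta, row_type = "saccade", sac_index = i,
            stats::setNames(as.data.frame(f[.res_sac]),
                            paste0("sac_", .res_sac)),
            position_error_deg = err)
    })
    c(list(imp), sac)
  })
  rows <- unlist(rows, recursive = FALSE)
  all_cols <- c(.res_meta, "row_type", paste0("imp_", .res_imp), .res_gain,
                "sac_index", paste0("sac_", .res_sac), "position_error_deg")
  df <- do.call(rbind, lapply(rows %||% list(), function(r) {
    for (nm in setdiff(all_cols, names(r))) r[[nm]] <- NA
    r[all_cols]
  }))
  if (is.null(df)) {
    df <- as.data.frame(stats::setNames(rep(list(logical(0)), length(all_cols)),
                                        all_cols))
  }
  utils::write.table(format_num_df(df), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a results TSV back into analysis records
#'
#' @param path results TSV written by [write_results()].
#' @return list of `result_record`.
#' @export
read_results <- function(path) {
  if (!file.exists(path))
    vorsac_stop("vorsac_io_error", sprintf("file not found: %s", path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!nrow(df)) return(list())
  ids <- unique(df$trial_id)
  lapply(ids, function(id) {
    rows <- df[df$trial_id == id, , drop = FALSE]
    ir <- rows[rows$row_type == "impulse", , drop = FALSE][1, ]
    imp <- structure(stats::setNames(as.list(ir[paste0("imp_", .res_imp)]),
                                     .res_imp), class = "impulse_segment")
    gn <- structure(as.list(ir[.res_gain]), class = "gain_result")
    sr <- rows[rows$row_type == "saccade", , drop = FALSE]
    sr <- sr[order(sr$sac_index), , drop = FALSE]
    sacc <- lapply(seq_len(nrow(sr)), function(i) {
      f <- stats::setNames(as.list(sr[i, paste0("sac_", .res_sac)]), .res_sac)
      f$seq_index <- if (is.na(f$seq_index)) NA_integer_ else as.integer(f$seq_index)
      structure(f, class = "saccade_fit")
    })
    pe <- if (nrow(sr)) {
      data.frame(saccade_index = seq_len(nrow(sr)),
                 onset_ms = sr$sac_onset_ms, error_deg = sr$position_error_deg)
    } else NULL
    rec <- structure(c(stats::setNames(as.list(ir[.res_meta]), .res_meta),
                       list(impulse = imp, gain = gn, saccades = sacc,
                            position_errors = pe)),
                     class = "result_record")
    rec
  })
}

#' @export
print.result_record <- function(x, ...) {
  cat(sprintf("trial %s (%s %s, %s, %s): gain %.3f, %d saccade(s)\n",
              x$trial_id, x$side, x$canal, x$condition, x$group,
              x$gain$gain, length(x$saccades)))
  invisible(x)
}
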