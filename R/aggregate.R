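#' Summarize analysis records by group, canal, condition and saccade number
#'
#' Produces one row per (group, canal, condition, saccade sequence index
#' 1..3) cell over the cells present in the records: number of accepted
#' impulses, saccade frequency (% of accepted impulses containing a
#' compensatory saccade of that index), mean amplitude and SEM (deg,
#' magnitudes), mean onset latency and SEM (ms), and latency clustering
#' (sample SD of onset latency, ms; `NA` with fewer than two saccades).
#'
#' Means and SEMs are plain saccade-level cell statistics; they do not
#' adjust for repeated measures within subjects the way marginal-mean
#' regression summaries would.
#'
#' @param records list of `result_record`.
#' @param max_seq highest saccade sequence index to tabulate.
#' @return data.frame of class `vhit_summary`.
#' @export
summarize_records <- function(records, max_seq = 3) {
  if (!length(records))
    return(structure(data.frame(), class = c("vhit_summary", "data.frame")))
  trial <- do.call(rbind, lapply(records, function(r)
    data.frame(trial_id = r$trial_id, group = r$group, canal = r$canal,
               condition = r$condition, stringsAsFactors = FALSE)))
  sac <- do.call(rbind, lapply(records, function(r) {
    comp <- Filter(function(f) identical(f$direction_class, "compensatory"),
                   r$saccades)
    if (!length(comp)) return(NULL)
    data.frame(trial_id = r$trial_id, group = r$group, canal = r$canal,
               condition = r$condition,
               seq_index = vapply(comp, `[[`, integer(1), "seq_index"),
               amplitude = abs(vapply(comp, `[[`, numeric(1), "amplitude_deg")),
               latency = vapply(comp, `[[`, numeric(1), "onset_latency_ms"),
               stringsAsFactors = FALSE)
  }))
  cells <- unique(trial[c("group", "canal", "condition")])
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    cell <- cells[i, ]
    in_cell <- trial$group == cell$group & trial$canal == cell$canal &
      trial$condition == cell$condition
    n_imp <- sum(in_cell)
    do.call(rbind, lapply(seq_len(max_seq), function(k) {
      s <- if (is.null(sac)) NULL else
        sac[sac$group == cell$group & sac$canal == cell$canal &
              sac$condition == cell$condition & sac$seq_index == k, ,
            drop = FALSE]
      n_s <- if (is.null(s)) 0L else nrow(s)
      data.frame(
        group = cell$group, canal = cell$canal, condition = cell$condition,
        seq_index = k, n_impulses = n_imp, n_saccades = n_s,
        frequency_pct = 100 * n_s / n_imp,
        amplitude_mean_deg = if (n_s) mean(s$amplitude) else NA_real_,
        amplitude_sem_deg = if (n_s > 1) stats::sd(s$amplitude) / sqrt(n_s) else NA_real_,
        latency_mean_ms = if (n_s) mean(s$latency) else NA_real_,
        latency_sem_ms = if (n_s > 1) stats::sd(s$latency) / sqrt(n_s) else NA_real_,
        clustering_ms = if (n_s > 1) stats::sd(s$latency) else NA_real_,
        stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  structure(out, class = c("vhit_summary", "data.frame"))
}

#' Count fitted compensatory saccades per sequence index
#'
#' @param records list of `result_record`.
#' @param max_seq highest sequence index to count.
#' @return data.frame with `seq_index`, `n` (total), `n_covert`,
#'   `n_overt`; the counts are consistent with summing the per-cell
#'   summary rows.
#' @export
count_saccade_totals <- function(records, max_seq = 3) {
  seqs <- unlist(lapply(records, function(r)
    vapply(Filter(function(f) identical(f$direction_class, "compensatory"),
                  r$saccades), `[[`, integer(1), "seq_index")))
  timing <- unlist(lapply(records, function(r)
    vapply(Filter(function(f) identical(f$direction_class, "compensatory"),
                  r$saccades), `[[`, character(1), "timing_class")))
  data.frame(seq_index = seq_len(max_seq),
             n = vapply(seq_len(max_seq), function(k) sum(seqs == k), integer(1)),
             n_covert = vapply(seq_len(max_seq), function(k)
               sum(seqs == k & timing == "covert"), integer(1)),
             n_overt = vapply(seq_len(max_seq), function(k)
               sum(seqs == k & timing == "overt"), integer(1)))
}

#' Write a summary table as TSV
#'
#' @param summary a `vhit_summary`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(summary, path) {
  utils::write.table(summary, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
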