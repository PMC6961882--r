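# Builders for deterministic single-trial fixtures used across test files.

# A clean (optionally noisy) trial: sin^2 impulse, proportional slow phase,
# and explicitly placed dual-Gaussian saccades.  `saccades` is a list of
# lists with amp (deg), lat (onset latency, ms, 5%-of-peak convention),
# sigma (ms), and optional ratio (B/A, default 0.3) and sign (+1 forces an
# anti-compensatory saccade).
make_trial <- function(gain = 0.5, vp = 200, dur = 150, bounce = 25,
                       direction = 1, noise = 0, saccades = list(),
                       fs = 250, pre = 200, total = 1000, id = "fixture") {
  prof <- generate_impulse_profile(vp, dur, bounce, direction, fs, pre, total)
  ve <- -gain * prof$v
  truth <- list()
  for (s in saccades) {
    ratio <- s$ratio %||% 0.3
    sgn <- s$sign %||% -direction
    A <- sgn * s$amp / ((1 - ratio) * (s$sigma / 1000) * sqrt(2 * pi))
    tp <- prof$onset_tangent_ms + s$lat -
      vorsac:::dg_onset_offset(s$sigma, ratio)
    ve <- ve + dual_gaussian(prof$t, A, ratio * A, tp, s$sigma)
    truth[[length(truth) + 1]] <- list(A = A, B = ratio * A, t_peak = tp,
                                       sigma = s$sigma, amp = sgn * s$amp,
                                       lat = s$lat)
  }
  if (noise > 0) ve <- ve + stats::rnorm(length(prof$t), 0, noise)
  list(trace = vhit_trace(id, prof$t, prof$v, ve, fs = fs),
       profile = prof, truth = truth)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# First compensatory saccade of each analyzed record, dropped records
# without one.
first_saccades <- function(records) {
  out <- lapply(records, function(r)
    Filter(function(f) identical(f$seq_index, 1L), r$saccades))
  unlist(out, recursive = FALSE)
}

analyze_batch_quiet <- function(traces) {
  vhit_analyze(traces, NULL, vhit_config(verbosity = 0))
}
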