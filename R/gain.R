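#' Position-ratio VOR gain
#'
#' The gain is the ratio of cumulative (integrated) eye to head velocity
#' over the window from 60 ms before peak head acceleration to the head
#' velocity zero crossing -- a position ratio.  By default the eye
#' velocity is desaccaded first (all fitted dual-Gaussian waveforms
#' subtracted) so that covert catch-up saccades do not inflate the gain;
#' set `desaccade = FALSE` for the raw ratio.
#'
#' A compensatory eye response (opposite the head) yields positive gain;
#' negative gains (possible in complete deafferentation) are reported
#' as-is.
#'
#' @param trace a `vhit_trace`.
#' @param impulse the detected `impulse_segment`.
#' @param fits list of `saccade_fit` (possibly empty).
#' @param desaccade subtract fitted saccades before integrating.
#' @param window_pre_ms window start relative to peak acceleration (ms).
#' @return object of class `gain_result`: `gain`, `window_start_ms`,
#'   `window_end_ms`, `eye_area_deg`, `head_area_deg`.
#' @export
compute_gain <- function(trace, impulse, fits = list(), desaccade = TRUE,
                         window_pre_ms = 60) {
  t <- trace$t
  a <- impulse$t_peak_acc_ms - window_pre_ms
  b <- impulse$t_zero_cross_ms
  if (a < t[1] || b > t[length(t)])
    vorsac_stop("vorsac_truncation_error", sprintf(
      "trial %s: gain window [%.1f, %.1f] ms exceeds trace bounds",
      trace$trial_id, a, b))
  ve <- trace$v_eye
  if (desaccade && length(fits)) {
    for (f in fits)
      ve <- ve - dual_gaussian(t, f$A, f$B, f$t_peak_ms, f$sigma_ms)
  }
  head_area <- trapz_window(t, trace$v_head, a, b) / 1000
  eye_area <- -trapz_window(t, ve, a, b) / 1000
  if (abs(head_area) < 1)
    vorsac_stop("vorsac_unstable_denominator", sprintf(
      "trial %s: cumulative head movement %.2f deg too small for a stable ratio",
      trace$trial_id, head_area))
  structure(list(gain = eye_area / head_area,
                 window_start_ms = a, window_end_ms = b,
                 eye_area_deg = eye_area, head_area_deg = head_area),
            class = "gain_result")
}

#' @export
print.gain_result <- function(x, ...) {
  cat(sprintf("VOR gain %.3f (eye %.2f deg / head %.2f deg over [%.1f, %.1f] ms)\n",
              x$gain, x$eye_area_deg, x$head_area_deg,
              x$window_start_ms, x$window_end_ms))
  invisible(x)
}

#' Visual position error at saccade onsets
#'
#' The gaze-in-space velocity is `v_head + v_eye`; its integral from
#' before the impulse approximates the gaze position error relative to the
#' earth-fixed target (zero for a perfect VOR).  Sensor drift is removed
#' by anchoring the integral to zero over a pre-impulse baseline and, when
#' at least 200 ms of saccade-free post-impulse tail exists, removing the
#' residual linear drift estimated from the tail slope (gaze is assumed
#' stationary there).  The error is reported at each saccade's onset,
#' signed so that positive means gaze lagging in the direction of the
#' head movement.
#'
#' @param trace a `vhit_trace`.
#' @param impulse the detected `impulse_segment`.
#' @param fits list of `saccade_fit` (used to locate saccade-free spans
#'   and to pick the report times).
#' @param baseline_ms pre-impulse anchoring window length (ms).
#' @return data.frame with `saccade_index`, `onset_ms`, `error_deg`; when
#'   `fits` is empty, a zero-row frame (the corrected position series is
#'   attached as attribute `"position"` for diagnostics).
#' @export
position_error_at_saccades <- function(trace, impulse, fits = list(),
                                       baseline_ms = 100) {
  t <- trace$t
  b0 <- impulse$onset_ms - baseline_ms
  base <- which(t >= b0 & t <= impulse$onset_ms)
  if (b0 < t[1] || length(base) < 5)
    vorsac_stop("vorsac_anchoring_error", sprintf(
      "trial %s: needs >= %g ms of pre-impulse baseline", trace$trial_id,
      baseline_ms))
  gaze <- trace$v_head + trace$v_eye
  pos <- pracma::cumtrapz(t / 1000, gaze)[, 1]

  m1 <- mean(pos[base])
  c1 <- mean(t[base])
  pos <- pos - m1

  # Saccade-free tail of >= 200 ms: estimate residual drift from its slope.
  tail_start <- t[length(t)] - 200
  busy_hi <- c(impulse$t_zero_cross_ms,
               vapply(fits, function(f) f$t_peak_ms + 6 * f$sigma_ms, numeric(1)))
  if (t[length(t)] - max(busy_hi) >= 200) {
    tail_i <- which(t >= tail_start)
    drift <- stats::coef(stats::lm(pos[tail_i] ~ t[tail_i]))[2]
    pos <- pos - drift * (t - c1)
  }

  if (!length(fits)) {
    out <- data.frame(saccade_index = integer(0), onset_ms = numeric(0),
                      error_deg = numeric(0))
  } else {
    onset <- vapply(fits, `[[`, numeric(1), "onset_ms")
    out <- data.frame(
      saccade_index = seq_along(fits),
      onset_ms = onset,
      error_deg = impulse$direction * vapply(onset, function(x)
        interp_at(t, pos, x), numeric(1)))
  }
  attr(out, "position") <- pos
  out
}
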