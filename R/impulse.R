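#' Impulse detection configuration
#'
#' @param log_sigma_ms Gaussian scale of the derivative filters (ms).
#'   Default 8 ms (two samples either side of centre at 250 Hz): small
#'   enough to preserve ~150 ms impulse dynamics, large enough to suppress
#'   sample noise.
#' @param min_peak_velocity minimum acceptable peak head velocity (deg/s).
#' @param max_peak_velocity maximum acceptable peak head velocity (deg/s).
#' @param max_duration_ms maximum acceptable impulse duration (ms).
#' @return list of class `impulse_config`.
#' @export
impulse_config <- function(log_sigma_ms = 8, min_peak_velocity = 100,
                           max_peak_velocity = 300, max_duration_ms = 200) {
  stopifnot(log_sigma_ms > 0, min_peak_velocity > 0,
            max_peak_velocity > min_peak_velocity, max_duration_ms > 0)
  structure(list(log_sigma_ms = log_sigma_ms,
                 min_peak_velocity = min_peak_velocity,
                 max_peak_velocity = max_peak_velocity,
                 max_duration_ms = max_duration_ms),
            class = "impulse_config")
}

#' Detect the head impulse in a trace
#'
#' Head acceleration is estimated with a Gaussian-derivative (LoG) filter;
#' the impulse onset is the time-axis intercept of the line tangent to the
#' head velocity at peak acceleration.  The impulse ends where head
#' velocity first recrosses zero after its peak; any opposite-sign
#' overshoot immediately after the zero crossing is reported as "bounce"
#' (% of peak velocity).
#'
#' Stimuli outside the configured envelope (peak velocity, duration) are
#' rejected with a classed condition carrying a `reason` field, replacing
#' the manual visual trace rejection used during clinical capture.
#'
#' @param trace a validated `vhit_trace`.
#' @param cfg an [impulse_config()].
#' @return object of class `impulse_segment` with fields `onset_ms`,
#'   `t_peak_acc_ms`, `t_peak_vel_ms`, `t_zero_cross_ms`, `direction`,
#'   `amplitude_deg`, `peak_velocity_dps`, `peak_acceleration_dps2`,
#'   `duration_ms`, `bounce_pct`.
#' @export
detect_impulse <- function(trace, cfg = impulse_config()) {
  validate_trace(trace)
  t <- trace$t; v <- trace$v_head
  ipk <- which.max(abs(v))
  if (abs(v[ipk]) < cfg$min_peak_velocity)
    vorsac_stop("vorsac_no_impulse",
                sprintf("trial %s: no suprathreshold head motion (peak %.1f < %g deg/s)",
                        trace$trial_id, abs(v[ipk]), cfg$min_peak_velocity),
                reason = "no_impulse")
  direction <- sign(v[ipk])

  acc <- log_gradient(v, trace$fs, cfg$log_sigma_ms, order = 1)

  # Peak acceleration on the rising phase (same side as the impulse).
  rise <- seq_len(ipk)
  ia <- rise[which.max(direction * acc[rise])]
  pk_a <- refine_peak(t, direction * acc, ia)
  t_pa <- pk_a[1]
  a_pk <- pk_a[2] * direction            # signed deg/s^2
  v_pa <- interp_at(t, v, t_pa)

  # Tangent through (t_pa, v(t_pa)) with slope a_pk; zero-velocity intercept.
  onset <- t_pa - (v_pa / a_pk) * 1000

  pk_v <- refine_peak(t, direction * v, ipk)
  t_pv <- pk_v[1]
  peak_vel <- pk_v[2]

  # First zero recrossing of head velocity after the velocity peak.
  s <- direction * v
  after <- if (ipk < length(v)) seq.int(ipk, length(v) - 1L) else integer(0)
  cross <- after[s[after] > 0 & s[after + 1L] <= 0]
  if (!length(cross))
    vorsac_stop("vorsac_truncation_error",
                sprintf("trial %s: head velocity never recrosses zero", trace$trial_id),
                reason = "truncated")
  i0 <- cross[1]
  t_zc <- t[i0] + (t[i0 + 1L] - t[i0]) * s[i0] / (s[i0] - s[i0 + 1L])

  if (!all(is.finite(c(onset, t_pa, t_pv, t_zc))))
    vorsac_stop("vorsac_truncation_error",
                sprintf("trial %s: degenerate impulse landmarks", trace$trial_id),
                reason = "truncated")
  if (!(onset < t_pa && t_pa < t_pv && t_pv < t_zc))
    vorsac_stop("vorsac_no_impulse",
                sprintf("trial %s: impulse landmarks out of order", trace$trial_id),
                reason = "landmark_order")

  amplitude <- trapz_window(t, abs(v), onset, t_zc) / 1000  # deg
  duration <- t_zc - onset

  # Opposite-sign lobe immediately after the zero crossing.
  bounce <- 0
  post <- which(t > t_zc)
  if (length(post)) {
    neg <- s[post] < 0
    if (any(neg)) {
      run_end <- if (all(neg)) length(post) else which(!neg)[1] - 1L
      if (run_end >= 1L)
        bounce <- min(100, 100 * max(-s[post[seq_len(run_end)]]) / peak_vel)
    }
  }

  if (peak_vel < cfg$min_peak_velocity || peak_vel > cfg$max_peak_velocity)
    vorsac_stop("vorsac_rejected",
                sprintf("trial %s: peak velocity %.1f deg/s outside [%g, %g]",
                        trace$trial_id, peak_vel, cfg$min_peak_velocity,
                        cfg$max_peak_velocity),
                reason = "peak_velocity")
  if (duration > cfg$max_duration_ms)
    vorsac_stop("vorsac_rejected",
                sprintf("trial %s: duration %.1f ms exceeds %g ms",
                        trace$trial_id, duration, cfg$max_duration_ms),
                reason = "duration")

  structure(list(onset_ms = onset, t_peak_acc_ms = t_pa, t_peak_vel_ms = t_pv,
                 t_zero_cross_ms = t_zc, direction = direction,
                 amplitude_deg = amplitude, peak_velocity_dps = peak_vel,
                 peak_acceleration_dps2 = abs(a_pk), duration_ms = duration,
                 bounce_pct = bounce),
            class = "impulse_segment")
}

#' @export
print.impulse_segment <- function(x, ...) {
  cat(sprintf(paste0("head impulse: onset %.1f ms, peak acc %.0f deg/s^2 @ %.1f ms,\n",
                     "  peak vel %.1f deg/s @ %.1f ms (direction %+d), zero cross %.1f ms\n",
                     "  amplitude %.1f deg, duration %.0f ms, bounce %.0f%%\n"),
              x$onset_ms, x$peak_acceleration_dps2, x$t_peak_acc_ms,
              x$peak_velocity_dps, x$t_peak_vel_ms, x$direction,
              x$t_zero_cross_ms, x$amplitude_deg, x$duration_ms, x$bounce_pct))
  invisible(x)
}
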