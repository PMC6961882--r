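#' Saccade localization and fitting configuration
#'
#' @param hp_cutoff_hz corner frequency (Hz) of the zero-phase high-pass
#'   `f_HP` in the fit cost.  Default 3 Hz: impulse slow-phase energy is
#'   concentrated below ~3 Hz (>=150 ms events) while 10-30 ms saccadic
#'   transients lie well above.
#' @param jerk_threshold minimum |jerk| (deg/s^3) at an eye-acceleration
#'   zero crossing for it to count as a saccade candidate, or `"auto"`:
#'   5x the median absolute baseline jerk, with a floor of 2e4 deg/s^3
#'   (the smallest clinically reported saccades, ~1.5 deg, have smoothed
#'   peak jerk an order of magnitude above the floor).
#' @param max_saccades cap on fitted saccades per trial.
#' @param min_latency_ms saccades with onset latency at or below this are
#'   excluded (micro-saccades from the fixation task); default 50 ms.
#' @param max_iter gradient-descent iteration cap.
#' @param tol convergence tolerance on the relative change in the cost J.
#' @param log_sigma_ms derivative-filter scale (ms) used for localization.
#' @param min_peak_dps smallest fitted |A| (deg/s) accepted as a real
#'   saccade; fits below it are treated as noise and discarded.
#' @return list of class `fit_config`.
#' @export
fit_config <- function(hp_cutoff_hz = 3, jerk_threshold = "auto",
                       max_saccades = 3, min_latency_ms = 50,
                       max_iter = 500, tol = 1e-6, log_sigma_ms = 8,
                       min_peak_dps = 25) {
  stopifnot(hp_cutoff_hz > 0, min_latency_ms >= 0, max_saccades >= 1,
            max_iter >= 1, tol > 0, log_sigma_ms > 0)
  if (!identical(jerk_threshold, "auto")) stopifnot(jerk_threshold > 0)
  structure(list(hp_cutoff_hz = hp_cutoff_hz, jerk_threshold = jerk_threshold,
                 max_saccades = max_saccades, min_latency_ms = min_latency_ms,
                 max_iter = max_iter, tol = tol, log_sigma_ms = log_sigma_ms,
                 min_peak_dps = min_peak_dps),
            class = "fit_config")
}

#' Dual-Gaussian saccade velocity waveform
#'
#' `A exp(-(t - t_peak)^2 / (2 sigma^2)) - B exp(-(t - t_peak - 2 sigma)^2 /
#' (2 sigma^2))`: the main lobe carries the saccade proper; the second,
#' opposite-sign lobe centred two widths later phenomenologically captures
#' the post-saccadic oscillation of the iris seen in pupil-tracking video
#' systems.
#'
#' @param t time grid (ms).
#' @param A main-lobe peak coefficient (deg/s); its sign is the saccade
#'   direction.
#' @param B oscillation-lobe coefficient (deg/s), same sign convention.
#' @param t_peak_ms centre of the main lobe (ms).
#' @param sigma_ms Gaussian width (ms), must be positive.
#' @return velocity series (deg/s) on `t`.
#' @export
dual_gaussian <- function(t, A, B, t_peak_ms, sigma_ms) {
  if (!is.finite(sigma_ms) || sigma_ms <= 0)
    vorsac_stop("vorsac_domain_error", "sigma_ms must be positive")
  u1 <- (t - t_peak_ms) / sigma_ms
  u2 <- (t - t_peak_ms - 2 * sigma_ms) / sigma_ms
  A * exp(-u1^2 / 2) - B * exp(-u2^2 / 2)
}

# Partial derivatives of the waveform w.r.t. (A, B, t_peak, sigma).
dual_gaussian_partials <- function(t, A, B, t_peak_ms, sigma_ms) {
  s <- sigma_ms
  u1 <- (t - t_peak_ms) / s
  u2 <- (t - t_peak_ms - 2 * s) / s
  g1 <- exp(-u1^2 / 2)
  g2 <- exp(-u2^2 / 2)
  cbind(A = g1,
        B = -g2,
        t_peak = (A * g1 * u1 - B * g2 * u2) / s,
        sigma = (A * g1 * u1^2 - B * g2 * (u2^2 + 2 * u2)) / s)
}

#' Numeric saccade metrics from fitted waveform parameters
#'
#' Evaluates the fitted waveform on a 0.1 ms grid spanning `t_peak +/- 6
#' sigma` and derives: amplitude (trapezoidal integral, deg; analytically
#' `(A - B) sigma sqrt(2 pi)`), peak velocity (max |v|, deg/s), and onset
#' (earliest time the waveform reaches 5% of peak velocity in the
#' main-lobe direction).
#'
#' @param A,B,t_peak_ms,sigma_ms dual-Gaussian parameters.
#' @return list with `amplitude_deg` (signed like `A`),
#'   `peak_velocity_dps`, `onset_ms`, `t_peak_vel_ms`.
#' @export
saccade_metrics <- function(A, B, t_peak_ms, sigma_ms) {
  tf <- seq(t_peak_ms - 6 * sigma_ms, t_peak_ms + 6 * sigma_ms, by = 0.1)
  v <- dual_gaussian(tf, A, B, t_peak_ms, sigma_ms)
  amplitude <- pracma::trapz(tf / 1000, v)
  dirn <- if (A >= 0) 1 else -1
  ipk <- which.max(dirn * v)
  peak <- abs(v[ipk])
  onset_i <- which(dirn * v >= 0.05 * peak)[1]
  list(amplitude_deg = amplitude, peak_velocity_dps = peak,
       onset_ms = tf[onset_i], t_peak_vel_ms = tf[ipk])
}

# Onset offset (onset_ms - t_peak_ms) of a unit dual-Gaussian with the
# given width and lobe ratio; used by the generator to realize a target
# onset latency under the same 5%-of-peak convention as the analyzer.
dg_onset_offset <- function(sigma_ms, b_ratio) {
  saccade_metrics(1, b_ratio, 0, sigma_ms)$onset_ms
}

# Shared construction of the windowed cost J and its analytic gradient.
# ve is the series being fitted (slow-phase-corrected eye velocity); the
# window [wlo, whi] is the integration core, padded on each side for the
# high-pass filter state.
build_objective <- function(t, ve, fs, hp_cutoff_hz, wlo, whi, pad = 60) {
  dt_s <- 1 / fs
  idx <- which(t >= wlo - pad & t <= whi + pad)
  tw <- t[idx]
  yw <- ve[idx]
  core <- tw >= wlo & tw <= whi
  L <- function(z) hp_filter(z, fs, hp_cutoff_hz)
  Ly <- L(yw)
  Jfun <- function(th) {
    # physical region: widths 2-40 ms; the oscillation lobe shares the
    # main lobe's sign and stays smaller (a wider/ flipped fit is a
    # merge of neighbouring saccades, not a saccade)
    if (th["sigma"] < 2 || th["sigma"] > 40 ||
        th["t_peak"] < tw[1] || th["t_peak"] > tw[length(tw)]) return(Inf)
    if (abs(th["A"]) > 0 && (th["B"] / th["A"] < -0.05 ||
                             th["B"] / th["A"] > 0.9)) return(Inf)
    m <- dual_gaussian(tw, th["A"], th["B"], th["t_peak"], th["sigma"])
    res <- Ly - L(m)
    sum(res[core]^2) * dt_s
  }
  gradfun <- function(th) {
    m <- dual_gaussian(tw, th["A"], th["B"], th["t_peak"], th["sigma"])
    P <- dual_gaussian_partials(tw, th["A"], th["B"], th["t_peak"], th["sigma"])
    res <- Ly - L(m)
    g <- vapply(1:4, function(k) {
      -2 * dt_s * sum(res[core] * L(P[, k])[core])
    }, numeric(1))
    names(g) <- names(th)
    g
  }
  list(Jfun = Jfun, gradfun = gradfun, tw = tw, yw = yw, core = core)
}

#' Evaluate the saccade cost J for arbitrary parameters
#'
#' Rebuilds the exact objective a fit minimized (same window, padding,
#' high-pass, and slow-phase correction) and evaluates it at the supplied
#' dual-Gaussian parameters.  Intended for independent cross-checks of
#' the optimizer, e.g. brute-force grid searches.
#'
#' @param trace a `vhit_trace`.
#' @param impulse the detected `impulse_segment`.
#' @param A,B,t_peak_ms,sigma_ms parameters to evaluate.
#' @param window_ms integration window `c(lo, hi)` in ms (a fit's
#'   `fit_window_ms`).
#' @param cfg a [fit_config()].
#' @param v_eye optional series override (as passed to the fit).
#' @param g0 slow-phase gain used for correction (a fit's `g0`); `NULL`
#'   re-estimates it.
#' @return scalar cost J.
#' @export
saccade_cost <- function(trace, impulse, A, B, t_peak_ms, sigma_ms,
                         window_ms, cfg = fit_config(), v_eye = NULL,
                         g0 = NULL) {
  ve <- v_eye %||% trace$v_eye
  g0 <- g0 %||%
    slow_phase_gain(list(t = trace$t, v_eye = ve, v_head = trace$v_head),
                    impulse)
  ob <- build_objective(trace$t, ve + g0 * trace$v_head, trace$fs,
                        cfg$hp_cutoff_hz, window_ms[1], window_ms[2])
  ob$Jfun(c(A = A, B = B, t_peak = t_peak_ms, sigma = sigma_ms))
}

# Robust slow-phase gain estimate: median of -v_eye / v_head over the
# impulse core (|v_head| >= 30% of peak).  Saccades corrupt only a
# minority of core samples, so the median stays anchored to the VOR.
slow_phase_gain <- function(trace, impulse) {
  core <- which(trace$t >= impulse$onset_ms & trace$t <= impulse$t_zero_cross_ms &
                  abs(trace$v_head) >= 0.3 * impulse$peak_velocity_dps)
  if (length(core) < 3) return(0)
  g <- stats::median(-trace$v_eye[core] / trace$v_head[core])
  max(min(g, 1.5), -0.5)
}

#' Localize saccade candidates in the eye velocity signal
#'
#' Candidates are zero crossings of the smoothed eye acceleration (crests
#' and valleys of eye velocity) whose jerk magnitude exceeds the
#' threshold.  Before differentiation, the predicted slow-phase component
#' `-g0 * v_head` (robust median-ratio gain `g0`) is removed so that the
#' VOR velocity crest does not masquerade as a saccade.  Candidates before
#' `impulse onset + min_latency_ms` are discarded.
#'
#' @param trace a `vhit_trace`.
#' @param impulse the detected `impulse_segment`.
#' @param cfg a [fit_config()].
#' @param v_eye optional eye-velocity override (used internally on
#'   residuals after earlier saccades have been subtracted).
#' @return data.frame with columns `time_ms`, `jerk` (signed, deg/s^3),
#'   sorted by time; zero rows when no candidate qualifies.
#' @export
localize_candidates <- function(trace, impulse, cfg = fit_config(),
                                v_eye = NULL) {
  t <- trace$t
  ve <- v_eye %||% trace$v_eye
  g0 <- slow_phase_gain(list(t = t, v_eye = ve, v_head = trace$v_head), impulse)
  r <- ve + g0 * trace$v_head

  acc <- log_gradient(r, trace$fs, cfg$log_sigma_ms, order = 1)
  jerk <- log_gradient(r, trace$fs, cfg$log_sigma_ms, order = 2)

  thr <- cfg$jerk_threshold
  if (identical(thr, "auto")) {
    base <- which(t < impulse$onset_ms - 20)
    if (length(base) < 10) base <- seq_len(min(10L, length(t)))
    thr <- max(5 * stats::median(abs(jerk[base])), 2e4)
  }

  i <- which(acc[-length(acc)] * acc[-1] < 0)
  if (!length(i)) return(data.frame(time_ms = numeric(0), jerk = numeric(0)))
  tc <- t[i] + (t[i + 1L] - t[i]) * acc[i] / (acc[i] - acc[i + 1L])
  jc <- ifelse(abs(jerk[i]) > abs(jerk[i + 1L]), jerk[i], jerk[i + 1L])

  keep <- abs(jc) > thr &
    tc > impulse$onset_ms + cfg$min_latency_ms &
    tc < t[length(t)] - 30    # too close to the trace end to fit a window
  out <- data.frame(time_ms = tc[keep], jerk = jc[keep])
  out[order(out$time_ms), , drop = FALSE]
}

#' Fit one dual-Gaussian saccade by minimizing the high-pass cost J
#'
#' `J = sum((f_HP * (v_eye - v_sac))^2) dt` over a window around the
#' candidate.  Because only the high-frequency error is penalized, the
#' smooth slow-phase signal under the saccade is preserved rather than
#' absorbed into the fit.  Minimization is deterministic gradient descent
#' with analytic gradients, diagonal parameter scaling, and backtracking
#' line search; initialization comes from the candidate (t_peak at the
#' candidate, A from the slow-phase-corrected velocity there, sigma from
#' the flanking jerk sign changes, which bracket a Gaussian lobe at
#' t_peak +/- sigma; B = 0.3 A).
#'
#' @param trace a `vhit_trace`.
#' @param candidate_ms candidate time from [localize_candidates()].
#' @param cfg a [fit_config()].
#' @param impulse the detected `impulse_segment` (onset reference).
#' @param v_eye optional residual eye velocity to fit instead of
#'   `trace$v_eye`.
#' @param remove_slow_phase subtract the predicted slow-phase component
#'   `-g0 * v_head` (robust median-ratio gain `g0`) before fitting.  The
#'   high-pass in J suppresses smooth low-frequency structure, but the
#'   sharper slow-phase response to the impulse bounce lobe (~D/2 long)
#'   retains enough high-frequency energy to bias fits; removing the
#'   predicted slow phase leaves the high-pass only the prediction
#'   *error* to absorb.
#' @param g0 optional slow-phase gain to use instead of the internal
#'   robust estimate (used by [fit_saccades()] to refit with a gain
#'   estimated on the fully desaccaded signal, which a covert saccade
#'   would otherwise contaminate).
#' @param neighbor_ms times (ms) of other candidate saccades.  Neighbors
#'   beyond the candidate's own structure (3.5 sigma0) shrink the fit
#'   window toward the half-distance, so that a fit cannot widen itself
#'   to swallow an adjacent saccade.
#' @return object of class `saccade_fit`: parameters `A`, `B`,
#'   `t_peak_ms`, `sigma_ms`; metrics `amplitude_deg`,
#'   `peak_velocity_dps`, `onset_ms`, `onset_latency_ms`; diagnostics
#'   `J`, `residual_rms`, `converged`, `n_iter`; classification slots
#'   filled by [classify_saccades()].
#' @export
fit_saccade <- function(trace, candidate_ms, cfg = fit_config(), impulse,
                        v_eye = NULL, remove_slow_phase = TRUE, g0 = NULL,
                        neighbor_ms = numeric(0)) {
  t <- trace$t
  ve <- v_eye %||% trace$v_eye
  fs <- trace$fs
  dt_s <- 1 / fs

  g0 <- g0 %||%
    slow_phase_gain(list(t = t, v_eye = ve, v_head = trace$v_head), impulse)
  r <- ve + g0 * trace$v_head
  if (remove_slow_phase) ve <- r

  # sigma0 from the jerk sign changes flanking the candidate: a Gaussian
  # velocity lobe centred at t_peak has jerk zero crossings at exactly
  # t_peak +/- sigma.
  jerk <- log_gradient(r, fs, cfg$log_sigma_ms, order = 2)
  zc_i <- which(jerk[-length(jerk)] * jerk[-1] < 0)
  zc_t <- t[zc_i] + (t[zc_i + 1L] - t[zc_i]) * jerk[zc_i] /
    (jerk[zc_i] - jerk[zc_i + 1L])
  before <- zc_t[zc_t < candidate_ms - 1]
  after <- zc_t[zc_t > candidate_ms + 1]
  sigma0 <- if (length(before) && length(after)) {
    ((candidate_ms - max(before)) + (min(after) - candidate_ms)) / 2
  } else 12
  sigma0 <- max(min(sigma0, 30), 5)

  A0 <- interp_at(t, r, candidate_ms)
  theta <- c(A = A0, B = 0.3 * A0, t_peak = candidate_ms, sigma = sigma0)

  pad <- 60
  half <- 6 * sigma0
  far <- abs(neighbor_ms - candidate_ms)
  far <- far[far > 3.5 * sigma0]
  if (length(far)) half <- min(half, max(3.5 * sigma0, 0.7 * min(far)))
  wlo <- candidate_ms - half
  whi <- candidate_ms + half
  idx <- which(t >= wlo - pad & t <= whi + pad)
  if (sum(t[idx] >= wlo & t[idx] <= whi) * 1000 / fs < 40)
    vorsac_stop("vorsac_window_error",
                sprintf("trial %s: fit window around %.0f ms has < 40 ms of data",
                        trace$trial_id, candidate_ms))
  ob <- build_objective(t, ve, fs, cfg$hp_cutoff_hz, wlo, whi, pad)
  Jfun <- ob$Jfun
  gradfun <- ob$gradfun
  tw <- ob$tw
  yw <- ob$yw
  core <- ob$core

  sc <- c(max(abs(A0), 50), max(abs(A0), 50) / 2, 5, 3)
  J <- Jfun(theta)
  if (!is.finite(J))
    vorsac_stop("vorsac_numeric_error",
                sprintf("trial %s: non-finite cost at initialization", trace$trial_id))
  alpha <- 1
  converged <- FALSE
  iter <- 0L
  while (iter < cfg$max_iter) {
    iter <- iter + 1L
    g <- gradfun(theta)
    gu <- g * sc
    gn2 <- sum(gu^2)
    if (gn2 < 1e-20) { converged <- TRUE; break }
    alpha <- min(alpha * 2, 1e3)
    Jnew <- Inf
    repeat {
      cand <- theta - alpha * gu * sc
      Jnew <- Jfun(cand)
      if (is.finite(Jnew) && Jnew <= J - 1e-4 * alpha * gn2) break
      alpha <- alpha / 2
      if (alpha < 1e-14) break
    }
    if (alpha < 1e-14) { converged <- TRUE; break }  # no descent direction left
    dJ <- J - Jnew
    theta <- cand
    J <- Jnew
    if (dJ / max(J, 1e-12) < cfg$tol) { converged <- TRUE; break }
  }

  m <- dual_gaussian(tw, theta["A"], theta["B"], theta["t_peak"], theta["sigma"])
  res_rms <- sqrt(mean((yw - m)[core]^2))
  met <- saccade_metrics(theta["A"], theta["B"], theta["t_peak"], theta["sigma"])

  structure(list(A = unname(theta["A"]), B = unname(theta["B"]),
                 t_peak_ms = unname(theta["t_peak"]),
                 sigma_ms = unname(theta["sigma"]),
                 amplitude_deg = met$amplitude_deg,
                 peak_velocity_dps = met$peak_velocity_dps,
                 onset_ms = met$onset_ms,
                 onset_latency_ms = met$onset_ms - impulse$onset_ms,
                 seq_index = NA_integer_, timing_class = NA_character_,
                 direction_class = NA_character_,
                 J = unname(J), residual_rms = res_rms,
                 converged = converged, n_iter = iter,
                 fit_window_ms = c(wlo, whi), g0 = g0),
            class = "saccade_fit")
}

#' Fit all saccades in a trial by greedy subtraction
#'
#' Repeatedly localizes candidates on the current residual, fits the
#' largest-jerk candidate, and subtracts the fitted waveform, up to
#' `max_saccades` per trial.  Fits whose main lobe is smaller than the
#' oscillation lobe or below `min_peak_dps` are discarded as noise.  The
#' returned fits are classified and sequenced (see
#' [classify_saccades()]).
#'
#' @param trace a `vhit_trace`.
#' @param impulse the detected `impulse_segment`.
#' @param cfg a [fit_config()].
#' @return list of `saccade_fit`, sorted by onset latency.
#' @export
fit_saccades <- function(trace, impulse, cfg = fit_config()) {
  v_work <- trace$v_eye
  fits <- list()
  banned <- numeric(0)
  while (length(fits) < cfg$max_saccades) {
    cand <- localize_candidates(trace, impulse, cfg, v_eye = v_work)
    if (length(banned) && nrow(cand))
      cand <- cand[vapply(cand$time_ms,
                          function(x) all(abs(x - banned) > 20), logical(1)), ,
                   drop = FALSE]
    if (!nrow(cand)) break
    top <- cand[which.max(abs(cand$jerk)), ]
    nbrs <- c(setdiff(cand$time_ms, top$time_ms),
              vapply(fits, `[[`, numeric(1), "t_peak_ms"))
    fit <- tryCatch(
      fit_saccade(trace, top$time_ms, cfg, impulse, v_eye = v_work,
                  neighbor_ms = nbrs),
      vorsac_window_error = function(e) NULL)
    banned <- c(banned, top$time_ms)
    if (is.null(fit)) next
    ok <- abs(fit$A) > abs(fit$B) && abs(fit$A) >= cfg$min_peak_dps &&
      fit$sigma_ms > 2 && fit$sigma_ms <= 40
    if (!ok) next
    fits[[length(fits) + 1L]] <- fit
    banned <- c(banned, fit$t_peak_ms)
    v_work <- v_work - dual_gaussian(trace$t, fit$A, fit$B,
                                     fit$t_peak_ms, fit$sigma_ms)
  }

  # Backfitting refinement: a covert saccade inflates the median-ratio
  # gain used for slow-phase removal, and overlapping saccades absorb
  # part of each other on the first greedy pass.  Re-estimate the gain on
  # the fully desaccaded signal and refit each saccade against the
  # residual of the others; two sweeps are enough for saccades >= 60 ms
  # apart.
  model_of <- function(f) dual_gaussian(trace$t, f$A, f$B, f$t_peak_ms,
                                        f$sigma_ms)
  for (sweep in seq_len(if (length(fits)) 2L else 0L)) {
    total <- Reduce(`+`, lapply(fits, model_of))
    g0c <- slow_phase_gain(list(t = trace$t, v_eye = trace$v_eye - total,
                                v_head = trace$v_head), impulse)
    all_tp <- vapply(fits, `[[`, numeric(1), "t_peak_ms")
    fits <- lapply(fits, function(f) {
      v_k <- trace$v_eye - (total - model_of(f))
      tryCatch(
        fit_saccade(trace, f$t_peak_ms, cfg, impulse, v_eye = v_k, g0 = g0c,
                    neighbor_ms = setdiff(all_tp, f$t_peak_ms)),
        vorsac_error = function(e) f)
    })
    fits <- Filter(function(f) abs(f$A) > abs(f$B) &&
                     abs(f$A) >= cfg$min_peak_dps, fits)
    if (!length(fits)) break
  }

  fits <- fits[order(vapply(fits, `[[`, numeric(1), "onset_latency_ms"))]
  classify_saccades(fits, impulse, cfg)
}

#' Classify and sequence fitted saccades
#'
#' Drops saccades at or below the minimum onset latency (micro-saccades),
#' labels direction (`compensatory` when the main lobe opposes the head
#' movement, else `anti_compensatory`), labels timing (`covert` when the
#' saccade peak falls within the head impulse, `overt` after it), and
#' assigns `seq_index` 1..n over compensatory saccades only, in onset
#' order.
#'
#' @param fits list of `saccade_fit`.
#' @param impulse the `impulse_segment` providing the onset and
#'   zero-crossing references.
#' @param cfg a [fit_config()].
#' @return filtered, annotated list sorted by onset latency.
#' @export
classify_saccades <- function(fits, impulse, cfg = fit_config()) {
  keep <- Filter(function(f) f$onset_latency_ms > cfg$min_latency_ms, fits)
  keep <- keep[order(vapply(keep, `[[`, numeric(1), "onset_latency_ms"))]
  seq_i <- 0L
  lapply(keep, function(f) {
    comp <- sign(f$A) == -impulse$direction
    f$direction_class <- if (comp) "compensatory" else "anti_compensatory"
    f$timing_class <- if (f$t_peak_ms <= impulse$t_zero_cross_ms) "covert" else "overt"
    if (comp) {
      seq_i <<- seq_i + 1L
      f$seq_index <- seq_i
    } else {
      f$seq_index <- NA_integer_
    }
    f
  })
}

#' @export
print.saccade_fit <- function(x, ...) {
  cat(sprintf(paste0("saccade fit: A %.1f, B %.1f deg/s, t_peak %.1f ms, ",
                     "sigma %.1f ms\n  amplitude %.2f deg, peak %.1f deg/s, ",
                     "onset latency %.1f ms\n  %s %s seq %s (J %.3g, %s in %d iter)\n"),
              x$A, x$B, x$t_peak_ms, x$sigma_ms, x$amplitude_deg,
              x$peak_velocity_dps, x$onset_latency_ms,
              x$timing_class %||% "?", x$direction_class %||% "?",
              ifelse(is.na(x$seq_index), "-", x$seq_index), x$J,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}
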