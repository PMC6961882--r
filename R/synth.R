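#' @title Synthetic vHIT trial generator
#' @name synth
#' @description Generates head-impulse trials with known ground truth:
#'   a sin^2 head-velocity lobe (optionally followed by an opposite-sign
#'   "bounce" lobe), an eye response `-gain * v_head`, injected
#'   dual-Gaussian compensatory saccades, and white velocity noise.  Every
#'   pipeline stage can thus be tested against the generating parameters.
NULL

two <- function(x, what) {
  if (length(x) == 1) x <- c(x, 0)
  if (length(x) != 2 || !all(is.finite(x)) || x[2] < 0)
    vorsac_stop("vorsac_validation_error",
                sprintf("%s must be c(mean, sd) with sd >= 0", what))
  x
}

#' Synthetic-cohort configuration
#'
#' @param n_trials number of trials to generate.
#' @param seed RNG seed; may be left `NULL` here but generation itself
#'   always requires one.
#' @param stimulus list with `peak_velocity`, `duration_ms`, `bounce_pct`
#'   (each `c(mean, sd)`) and `direction` ("alternate", "random",
#'   "positive").
#' @param vor_gain `c(mean, sd)` of the per-trial VOR gain.
#' @param saccades list of saccade regimes, each a list with
#'   `probability` (marginal per-impulse injection probability),
#'   `amplitude` (deg, `c(mean, sd)`), `sigma_ms`, `latency_ms` (onset
#'   latency relative to impulse onset, 5%-of-peak convention), and
#'   `b_ratio` (oscillation/main lobe, default 0.3).  Regime k is
#'   injected only when regime k-1 was (a later saccade corrects an
#'   earlier one), with conditional probability `p_k / p_{k-1}`.
#' @param noise_sd_dps white velocity noise SD added to the eye channel.
#' @param fs sampling rate (Hz).
#' @param pre_ms pre-impulse baseline length (ms).
#' @param total_ms total trial length (ms).
#' @param canal,side,condition,group metadata stamped on the traces.
#' @param description free-text provenance note.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n_trials = 100, seed = NULL,
                         stimulus = list(peak_velocity = c(204, 45.6),
                                         duration_ms = c(154, 16.2),
                                         bounce_pct = c(33, 16.6),
                                         direction = "alternate"),
                         vor_gain = c(0.93, 0.03),
                         saccades = list(),
                         noise_sd_dps = 3, fs = 250,
                         pre_ms = 200, total_ms = 1000,
                         canal = "lateral", side = "left",
                         condition = "light", group = "normal",
                         description = "") {
  stopifnot(n_trials >= 1, fs > 0, noise_sd_dps >= 0,
            pre_ms >= 120, total_ms > pre_ms + 400)
  stimulus$peak_velocity <- two(stimulus$peak_velocity, "stimulus$peak_velocity")
  stimulus$duration_ms <- two(stimulus$duration_ms, "stimulus$duration_ms")
  stimulus$bounce_pct <- two(stimulus$bounce_pct, "stimulus$bounce_pct")
  stimulus$direction <- stimulus$direction %||% "alternate"
  stopifnot(stimulus$direction %in% c("alternate", "random", "positive"))
  vor_gain <- two(vor_gain, "vor_gain")
  saccades <- lapply(saccades, function(s) {
    if (is.null(s$probability) || s$probability < 0 || s$probability > 1)
      vorsac_stop("vorsac_validation_error",
                  "saccade probability must be in [0, 1]")
    s$amplitude <- two(s$amplitude, "saccade amplitude")
    s$sigma_ms <- two(s$sigma_ms %||% c(12, 2), "saccade sigma_ms")
    s$latency_ms <- two(s$latency_ms, "saccade latency_ms")
    s$b_ratio <- s$b_ratio %||% 0.3
    stopifnot(s$b_ratio >= 0, s$b_ratio < 1)
    s
  })
  structure(list(n_trials = n_trials, seed = seed, stimulus = stimulus,
                 vor_gain = vor_gain, saccades = saccades,
                 noise_sd_dps = noise_sd_dps, fs = fs, pre_ms = pre_ms,
                 total_ms = total_ms, canal = canal, side = side,
                 condition = condition, group = group,
                 description = description),
            class = "synth_config")
}

#' Synthetic head-impulse velocity profile
#'
#' Main lobe `v(tau) = Vp sin^2(pi tau / D)` for `tau` in `[0, D]`,
#' followed by an opposite-sign sin^2 bounce lobe of peak
#' `bounce_pct% * Vp` and duration `D/2`.  The main-lobe amplitude is
#' `Vp * D / 2` in closed form, and the tangent-intercept onset (the
#' detector's definition) is at `tau = D (1/4 - 1/(2 pi))`.
#'
#' @param peak_velocity peak head velocity Vp (deg/s), in (0, 400].
#' @param duration_ms main-lobe duration D (ms), < 250.
#' @param bounce_pct bounce peak as % of Vp (0 disables the lobe).
#' @param direction +1 or -1.
#' @param fs sampling rate (Hz).
#' @param pre_ms baseline before the lobe starts (ms).
#' @param total_ms total length (ms).
#' @return list with `t` (ms), `v` (deg/s), and analytic landmarks
#'   `onset_tangent_ms`, `t_zero_cross_ms`, `amplitude_deg`.
#' @export
generate_impulse_profile <- function(peak_velocity, duration_ms, bounce_pct = 0,
                                     direction = 1, fs = 250, pre_ms = 200,
                                     total_ms = 1000) {
  if (!(peak_velocity > 0 && peak_velocity <= 400))
    vorsac_stop("vorsac_domain_error", "peak_velocity must be in (0, 400] deg/s")
  if (!(duration_ms > 0 && duration_ms < 250))
    vorsac_stop("vorsac_domain_error", "duration_ms must be in (0, 250) ms")
  if (bounce_pct < 0 || bounce_pct > 100)
    vorsac_stop("vorsac_domain_error", "bounce_pct must be in [0, 100]")
  stopifnot(direction %in% c(-1, 1))
  t <- seq(0, total_ms, by = 1000 / fs)
  tau <- t - pre_ms
  v <- numeric(length(t))
  main <- tau >= 0 & tau <= duration_ms
  v[main] <- peak_velocity * sin(pi * tau[main] / duration_ms)^2
  if (bounce_pct > 0) {
    bn <- tau > duration_ms & tau <= 1.5 * duration_ms
    v[bn] <- -(bounce_pct / 100) * peak_velocity *
      sin(pi * (tau[bn] - duration_ms) / (duration_ms / 2))^2
  }
  list(t = t, v = direction * v,
       onset_tangent_ms = pre_ms + duration_ms * (0.25 - 1 / (2 * pi)),
       t_zero_cross_ms = pre_ms + duration_ms,
       amplitude_deg = peak_velocity * duration_ms / 2000)
}

rnorm_clamp <- function(n, ms, lo, hi) {
  pmin(pmax(stats::rnorm(n, ms[1], ms[2]), lo), hi)
}

#' Generate one synthetic trial (uses the current RNG state)
#'
#' @param cfg a [synth_config()].
#' @param trial_id identifier for the emitted trace.
#' @param direction impulse direction (+1/-1).
#' @return list with `trace` (a `vhit_trace`) and `truth` (drawn gain,
#'   analytic impulse landmarks, injected saccade parameters with onset
#'   latencies under the 5%-of-peak convention).
#' @export
generate_trial <- function(cfg, trial_id = "trial_1", direction = 1) {
  vp <- rnorm_clamp(1, cfg$stimulus$peak_velocity, 50, 395)
  dur <- rnorm_clamp(1, cfg$stimulus$duration_ms, 80, 245)
  bon <- rnorm_clamp(1, cfg$stimulus$bounce_pct, 0, 80)
  gain <- stats::rnorm(1, cfg$vor_gain[1], cfg$vor_gain[2])

  prof <- generate_impulse_profile(vp, dur, bon, direction, cfg$fs,
                                   cfg$pre_ms, cfg$total_ms)
  t <- prof$t
  v_eye <- -gain * prof$v

  sacc <- list()
  prev_onset <- -Inf
  prev_p <- 1
  for (k in seq_along(cfg$saccades)) {
    s <- cfg$saccades[[k]]
    p_cond <- if (k == 1) s$probability else min(1, s$probability / max(prev_p, 1e-9))
    injected <- length(sacc) == (k - 1L) && stats::runif(1) < p_cond
    prev_p <- s$probability
    if (!injected) break
    amp <- rnorm_clamp(1, s$amplitude, 0.5, 25)
    sg <- rnorm_clamp(1, s$sigma_ms, 5, 30)
    lat <- rnorm_clamp(1, s$latency_ms, 55, cfg$total_ms - cfg$pre_ms - 250)
    onset_abs <- prof$onset_tangent_ms + lat
    # saccadic refractory period: successive onsets at least 100 ms apart
    if (onset_abs <= prev_onset + 100) onset_abs <- prev_onset + 100
    A <- -direction * amp / ((1 - s$b_ratio) * (sg / 1000) * sqrt(2 * pi))
    B <- s$b_ratio * A
    tp <- onset_abs - dg_onset_offset(sg, s$b_ratio)
    v_eye <- v_eye + dual_gaussian(t, A, B, tp, sg)
    sacc[[k]] <- data.frame(index = k, amplitude_deg = amp, sigma_ms = sg,
                            latency_ms = onset_abs - prof$onset_tangent_ms,
                            onset_ms = onset_abs, A = A, B = B, t_peak_ms = tp)
    prev_onset <- onset_abs
  }
  if (cfg$noise_sd_dps > 0)
    v_eye <- v_eye + stats::rnorm(length(t), 0, cfg$noise_sd_dps)

  trace <- vhit_trace(trial_id, t, prof$v, v_eye, fs = cfg$fs,
                      canal = cfg$canal, side = cfg$side,
                      condition = cfg$condition, group = cfg$group)
  truth <- list(trial_id = trial_id, gain = gain, direction = direction,
                peak_velocity_dps = vp, duration_ms = dur, bounce_pct = bon,
                onset_ms = prof$onset_tangent_ms,
                t_zero_cross_ms = prof$t_zero_cross_ms,
                saccades = if (length(sacc)) do.call(rbind, sacc) else
                  data.frame(index = integer(0), amplitude_deg = numeric(0),
                             sigma_ms = numeric(0), latency_ms = numeric(0),
                             onset_ms = numeric(0), A = numeric(0),
                             B = numeric(0), t_peak_ms = numeric(0)))
  list(trace = trace, truth = truth)
}

#' Generate a seeded batch of synthetic trials
#'
#' Fully deterministic: the same `cfg` and seed reproduce the identical
#' batch.  The caller's RNG state is restored afterwards.
#'
#' @param cfg a [synth_config()].
#' @param seed integer seed; defaults to `cfg$seed` and is mandatory.
#' @param id_prefix prefix for trial identifiers.
#' @return list with `traces` (list of `vhit_trace`) and `truth`
#'   (list of per-trial ground-truth records).
#' @export
generate_batch <- function(cfg, seed = cfg$seed, id_prefix = "trial") {
  if (is.null(seed) || !is.finite(seed))
    vorsac_stop("vorsac_validation_error", "generation requires an integer seed")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  dirs <- switch(cfg$stimulus$direction,
                 alternate = rep_len(c(1, -1), cfg$n_trials),
                 random = sample(c(1, -1), cfg$n_trials, replace = TRUE),
                 positive = rep(1, cfg$n_trials))
  out <- lapply(seq_len(cfg$n_trials), function(i)
    generate_trial(cfg, sprintf("%s_%04d", id_prefix, i), dirs[i]))
  list(traces = lapply(out, `[[`, "trace"),
       truth = lapply(out, `[[`, "truth"))
}
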