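test_that("all-zero head velocity raises a no-impulse error", {
  t <- seq(0, 996, by = 4)
  tr <- vhit_trace("flat", t, rep(0, length(t)), rep(0, length(t)))
  expect_error(detect_impulse(tr), class = "vorsac_no_impulse")
})

test_that("onset matches the analytic tangent intercept of a sin^2 pulse", {
  # For v = Vp sin^2(pi tau / D), peak acceleration is at tau = D/4 and the
  # tangent there crosses zero at tau = D (1/4 - 1/(2 pi)).
  tri <- make_trial(gain = 0, vp = 200, dur = 150, bounce = 0)
  imp <- detect_impulse(tri$trace)
  expect_lt(abs(imp$onset_ms - tri$profile$onset_tangent_ms), 4)
  expect_equal(imp$peak_velocity_dps, 200, tolerance = 1 / 200)
  expect_equal(imp$t_zero_cross_ms, tri$profile$t_zero_cross_ms, tolerance = 1)
  expect_equal(imp$duration_ms,
               tri$profile$t_zero_cross_ms - tri$profile$onset_tangent_ms,
               tolerance = 4)
  expect_identical(imp$direction, 1)
})

test_that("landmark ordering invariant holds on noisy batches", {
  cfg <- synth_config(n_trials = 15, vor_gain = c(0.9, 0), saccades = list(),
                      noise_sd_dps = 3)
  batch <- generate_batch(cfg, seed = 21)
  for (tr in batch$traces) {
    imp <- tryCatch(detect_impulse(tr), vorsac_rejected = function(e) NULL)
    if (is.null(imp)) next
    expect_true(imp$onset_ms < imp$t_peak_acc_ms)
    expect_true(imp$t_peak_acc_ms < imp$t_peak_vel_ms)
    expect_true(imp$t_peak_vel_ms < imp$t_zero_cross_ms)
    expect_gt(imp$duration_ms, 0)
  }
})

test_that("detection is translation-equivariant and mirror-symmetric", {
  set.seed(9)
  tri <- make_trial(gain = 0.4, vp = 220, dur = 160, bounce = 30, noise = 2)
  imp <- detect_impulse(tri$trace)

  shift <- 80
  tr_sh <- vhit_trace("sh", tri$trace$t + shift, tri$trace$v_head,
                      tri$trace$v_eye)
  imp_sh <- detect_impulse(tr_sh)
  for (f in c("onset_ms", "t_peak_acc_ms", "t_peak_vel_ms", "t_zero_cross_ms"))
    expect_equal(imp_sh[[f]], imp[[f]] + shift, tolerance = 1e-9)
  expect_equal(imp_sh$amplitude_deg, imp$amplitude_deg, tolerance = 1e-9)

  tr_mir <- vhit_trace("mir", tri$trace$t, -tri$trace$v_head, -tri$trace$v_eye)
  imp_mir <- detect_impulse(tr_mir)
  expect_identical(imp_mir$direction, -imp$direction)
  expect_equal(imp_mir$peak_velocity_dps, imp$peak_velocity_dps,
               tolerance = 1e-9)
  expect_equal(imp_mir$amplitude_deg, imp$amplitude_deg, tolerance = 1e-9)
  expect_equal(imp_mir$onset_ms, imp$onset_ms, tolerance = 1e-9)
  expect_equal(imp_mir$bounce_pct, imp$bounce_pct, tolerance = 1e-9)
})

test_that("bounce is measured as % of peak velocity and zero without overshoot", {
  tri30 <- make_trial(gain = 0, vp = 200, dur = 150, bounce = 30)
  expect_equal(detect_impulse(tri30$trace)$bounce_pct, 30, tolerance = 2)
  tri0 <- make_trial(gain = 0, vp = 200, dur = 150, bounce = 0)
  expect_equal(detect_impulse(tri0$trace)$bounce_pct, 0, tolerance = 0.5)
})

test_that("out-of-envelope stimuli are rejected with reason codes", {
  fast <- make_trial(vp = 350, dur = 150)
  err <- tryCatch(detect_impulse(fast$trace), vorsac_rejected = identity)
  expect_identical(err$reason, "peak_velocity")
  long <- make_trial(vp = 200, dur = 230)
  err2 <- tryCatch(detect_impulse(long$trace),
                   vorsac_rejected = identity)
  expect_identical(err2$reason, "duration")
})

test_that("a velocity plateau that never recrosses zero raises a truncation error", {
  t <- seq(0, 996, by = 4)
  v <- 200 / (1 + exp(-(t - 300) / 20))   # sigmoid rise, no return
  tr <- vhit_trace("trunc", t, v, -0.5 * v)
  expect_error(detect_impulse(tr), class = "vorsac_truncation_error")
})

test_that("detector-measured stimulus statistics match generator settings", {
  cfg <- synth_config(n_trials = 60, vor_gain = c(0.93, 0), saccades = list(),
                      noise_sd_dps = 3)
  batch <- generate_batch(cfg, seed = 33)
  try_imp <- function(tr) tryCatch(detect_impulse(tr),
                                   vorsac_error = function(e) NULL)
  imps <- Filter(Negate(is.null), lapply(batch$traces, try_imp))
  expect_gt(length(imps), 50)
  pv <- vapply(imps, `[[`, numeric(1), "peak_velocity_dps")
  am <- vapply(imps, `[[`, numeric(1), "amplitude_deg")
  # envelope acceptance truncates the tails, so compare against the
  # detector-accepted generator truths rather than the raw nominal mean
  ids <- vapply(batch$traces, function(tr) !is.null(try_imp(tr)), logical(1))
  tru <- batch$truth[ids]
  tv <- vapply(tru, `[[`, numeric(1), "peak_velocity_dps")
  td <- vapply(tru, `[[`, numeric(1), "duration_ms")
  expect_equal(mean(pv), mean(tv), tolerance = 0.02)
  expect_equal(mean(am), mean(tv * td / 2000), tolerance = 0.05)
})
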