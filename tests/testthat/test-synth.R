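test_that("sin^2 profile has the closed-form amplitude and landmarks", {
  prof <- generate_impulse_profile(200, 150, 0, 1, 250)
  # amplitude = Vp * D / 2 = 200 deg/s * 0.075 s = 15 deg
  expect_equal(prof$amplitude_deg, 15)
  expect_equal(pracma::trapz(prof$t / 1000, prof$v), 15, tolerance = 1e-3)
  expect_equal(prof$t_zero_cross_ms - 200, 150)
  expect_equal(prof$onset_tangent_ms, 200 + 150 * (0.25 - 1 / (2 * pi)))
  expect_error(generate_impulse_profile(500, 150), class = "vorsac_domain_error")
  expect_error(generate_impulse_profile(200, 260), class = "vorsac_domain_error")
})

test_that("generator bounce settings agree with the detector's definition", {
  tri <- generate_impulse_profile(200, 150, 30, 1, 250)
  tr <- vhit_trace("b", tri$t, tri$v, -0.9 * tri$v)
  expect_equal(detect_impulse(tr)$bounce_pct, 30, tolerance = 2)
})

test_that("gain 1 with no saccades and no noise negates the head exactly", {
  cfg <- synth_config(n_trials = 2, vor_gain = c(1, 0), saccades = list(),
                      noise_sd_dps = 0)
  batch <- generate_batch(cfg, seed = 8)
  for (tr in batch$traces) expect_identical(tr$v_eye, -tr$v_head)
})

test_that("identical seeds reproduce identical batches, different seeds differ", {
  cfg <- scenario_presets("bvl_light_lateral", n_trials = 5)
  b1 <- generate_batch(cfg, seed = 123)
  b2 <- generate_batch(cfg, seed = 123)
  expect_identical(b1, b2)
  b3 <- generate_batch(cfg, seed = 124)
  expect_false(identical(b1$traces[[1]]$v_eye, b3$traces[[1]]$v_eye))
})

test_that("generation without a seed is refused", {
  cfg <- synth_config(n_trials = 2)
  expect_error(generate_batch(cfg), class = "vorsac_validation_error")
})

test_that("injection counts follow the configured Bernoulli probability", {
  p <- 0.7
  cfg <- synth_config(n_trials = 400, vor_gain = c(0.3, 0),
                      saccades = list(list(probability = p,
                                           amplitude = c(5, 1),
                                           sigma_ms = c(12, 1),
                                           latency_ms = c(200, 30))),
                      noise_sd_dps = 0)
  batch <- generate_batch(cfg, seed = 99)
  n_inj <- sum(vapply(batch$truth, function(x) nrow(x$saccades) > 0, logical(1)))
  se <- sqrt(400 * p * (1 - p))
  expect_lt(abs(n_inj - 400 * p), 3 * se)
})

test_that("nested injection makes later saccades require earlier ones", {
  cfg <- synth_config(n_trials = 150, vor_gain = c(0.3, 0),
                      saccades = list(list(probability = 0.6,
                                           amplitude = c(6, 1),
                                           sigma_ms = c(12, 1),
                                           latency_ms = c(160, 20)),
                                      list(probability = 0.3,
                                           amplitude = c(3, 1),
                                           sigma_ms = c(12, 1),
                                           latency_ms = c(320, 30))),
                      noise_sd_dps = 0)
  batch <- generate_batch(cfg, seed = 101)
  counts <- vapply(batch$truth, function(x) nrow(x$saccades), integer(1))
  expect_true(all(counts %in% 0:2))
  # marginal ordering: first saccades at least as common as second
  expect_gte(sum(counts >= 1), sum(counts >= 2))
  # onsets strictly ordered within trials
  for (x in batch$truth) {
    if (nrow(x$saccades) == 2)
      expect_gt(x$saccades$onset_ms[2], x$saccades$onset_ms[1])
  }
})

test_that("ground-truth latency follows the analyzer's onset convention", {
  cfg <- synth_config(n_trials = 1, vor_gain = c(0.3, 0),
                      saccades = list(list(probability = 1,
                                           amplitude = c(6, 0),
                                           sigma_ms = c(12, 0),
                                           latency_ms = c(180, 0))),
                      noise_sd_dps = 0)
  batch <- generate_batch(cfg, seed = 13)
  s <- batch$truth[[1]]$saccades
  met <- saccade_metrics(s$A, s$B, s$t_peak_ms, s$sigma_ms)
  expect_equal(met$onset_ms - batch$truth[[1]]$onset_ms, s$latency_ms,
               tolerance = 0.15)
})

test_that("preset catalogue is complete and passes validation", {
  ps <- scenario_presets()
  expect_length(ps, 30)   # 5 groups x 2 conditions x 3 canals
  for (p in ps) expect_s3_class(p, "synth_config")
  expect_equal(scenario_presets("normal_light_lateral")$vor_gain[1], 0.93)
  expect_equal(scenario_presets("bvl_light_lateral")$saccades[[1]]$amplitude[1],
               7.0)
  expect_equal(scenario_presets("uvd_ipsi_light_lateral")$saccades[[1]]$probability,
               0.983)
  expect_error(scenario_presets("nope"), class = "vorsac_lookup_error")
})

test_that("generated cohorts respect the published stimulus envelope", {
  cfg <- scenario_presets("normal_light_lateral", n_trials = 100,
                          noise_sd_dps = 3)
  batch <- generate_batch(cfg, seed = 7)
  ok <- vapply(batch$truth, function(x)
    x$peak_velocity_dps >= 100 && x$peak_velocity_dps <= 300 &&
      x$duration_ms < 200, logical(1))
  expect_gte(mean(ok), 0.95)
})
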