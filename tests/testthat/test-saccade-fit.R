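test_that("pure slow-phase traces yield no candidates", {
  tri <- make_trial(gain = 0.9, bounce = 30)
  imp <- detect_impulse(tri$trace)
  cand <- localize_candidates(tri$trace, imp, fit_config())
  expect_identical(nrow(cand), 0L)
})

test_that("injected saccades are localized at their velocity peaks", {
  tri <- make_trial(gain = 0.4, noise = 0,
                    saccades = list(list(amp = 6, lat = 170, sigma = 12)))
  imp <- detect_impulse(tri$trace)
  cand <- localize_candidates(tri$trace, imp, fit_config())
  main <- cand[which.max(abs(cand$jerk)), ]
  expect_lt(abs(main$time_ms - tri$truth[[1]]$t_peak), 8)

  tri2 <- make_trial(gain = 0.4, noise = 0,
                     saccades = list(list(amp = 6, lat = 160, sigma = 12),
                                     list(amp = 4, lat = 280, sigma = 12)))
  imp2 <- detect_impulse(tri2$trace)
  cand2 <- localize_candidates(tri2$trace, imp2, fit_config())
  # both main lobes present, in temporal order
  hits <- vapply(tri2$truth, function(s)
    any(abs(cand2$time_ms - s$t_peak) < 8), logical(1))
  expect_true(all(hits))
  expect_false(is.unsorted(cand2$time_ms))
})

test_that("candidates before impulse onset + 50 ms are discarded", {
  tri <- make_trial(gain = 0.4, noise = 0,
                    saccades = list(list(amp = 6, lat = 30, sigma = 10)))
  imp <- detect_impulse(tri$trace)
  cand <- localize_candidates(tri$trace, imp, fit_config())
  expect_true(all(cand$time_ms > imp$onset_ms + 50))
})

test_that("noise-free dual-Gaussian is recovered to 0.1% by the descent", {
  tri <- make_trial(gain = 0.36, bounce = 30, noise = 0,
                    saccades = list(list(amp = 6.016, lat = 195, sigma = 12)))
  imp <- detect_impulse(tri$trace)
  fits <- fit_saccades(tri$trace, imp, fit_config())
  expect_length(fits, 1)
  f <- fits[[1]]
  s <- tri$truth[[1]]
  expect_equal(f$A, s$A, tolerance = 1e-3)
  expect_equal(f$B, s$B, tolerance = 1e-2)
  expect_equal(f$t_peak_ms, s$t_peak, tolerance = 1e-3)
  expect_equal(f$sigma_ms, s$sigma, tolerance = 1e-3)
  expect_true(f$converged)
})

test_that("descent cost matches a matched-objective coarse grid search", {
  set.seed(77)
  tri <- make_trial(gain = 0.3, noise = 5,
                    saccades = list(list(amp = 6, lat = 200, sigma = 12)))
  imp <- detect_impulse(tri$trace)
  fits <- fit_saccades(tri$trace, imp, fit_config())
  f <- fits[[1]]
  grid_min <- Inf
  for (A in seq(f$A * 0.85, f$A * 1.15, length.out = 7))
    for (B in seq(f$B * 0.5, f$B * 1.5, length.out = 5))
      for (tp in f$t_peak_ms + seq(-5, 5, length.out = 7))
        for (sg in seq(f$sigma_ms * 0.85, f$sigma_ms * 1.15, length.out = 5)) {
          J <- saccade_cost(tri$trace, imp, A, B, tp, sg, f$fit_window_ms,
                            fit_config(), g0 = f$g0)
          grid_min <- min(grid_min, J)
        }
  expect_lte(f$J, 1.01 * grid_min)
})

test_that("three staggered saccades are recovered with their sequence indices", {
  tri <- make_trial(gain = 0.3, noise = 0,
                    saccades = list(list(amp = 6, lat = 150, sigma = 12),
                                    list(amp = 3, lat = 300, sigma = 12),
                                    list(amp = 1.5, lat = 450, sigma = 10)))
  imp <- detect_impulse(tri$trace)
  fits <- fit_saccades(tri$trace, imp, fit_config())
  comp <- Filter(function(f) identical(f$direction_class, "compensatory"), fits)
  expect_length(comp, 3)
  expect_identical(vapply(comp, `[[`, integer(1), "seq_index"), 1:3)
  for (k in 1:3) {
    expect_lt(abs(abs(comp[[k]]$amplitude_deg) - abs(tri$truth[[k]]$amp)) /
                abs(tri$truth[[k]]$amp), 0.10)
  }
})

test_that("overlapping saccades 60 ms apart are both recovered within 20%", {
  set.seed(16)
  tri <- make_trial(gain = 0.3, noise = 3,
                    saccades = list(list(amp = 6, lat = 160, sigma = 12),
                                    list(amp = 4, lat = 220, sigma = 12)))
  imp <- detect_impulse(tri$trace)
  fits <- fit_saccades(tri$trace, imp, fit_config())
  comp <- Filter(function(f) identical(f$direction_class, "compensatory"), fits)
  expect_length(comp, 2)
  for (k in 1:2) {
    expect_lt(abs(abs(comp[[k]]$amplitude_deg) - abs(tri$truth[[k]]$amp)) /
                abs(tri$truth[[k]]$amp), 0.20)
  }
})

test_that("desaccading preserves the slow phase on noise-free trials", {
  tri <- make_trial(gain = 0.5, bounce = 30, noise = 0,
                    saccades = list(list(amp = 6, lat = 120, sigma = 12)))
  imp <- detect_impulse(tri$trace)
  fits <- fit_saccades(tri$trace, imp, fit_config())
  expect_length(fits, 1)
  f <- fits[[1]]
  resid <- tri$trace$v_eye -
    dual_gaussian(tri$trace$t, f$A, f$B, f$t_peak_ms, f$sigma_ms)
  slow <- -0.5 * tri$trace$v_head
  active <- abs(slow) > 1
  expect_gt(stats::cor(resid[active], slow[active]), 0.98)
})

test_that("classification applies the 50 ms floor, direction and timing rules", {
  imp <- list(onset_ms = 213, t_zero_cross_ms = 350, direction = 1)
  mk_fit <- function(A, lat, tp) {
    structure(list(A = A, B = 0.3 * A, t_peak_ms = tp, sigma_ms = 12,
                   amplitude_deg = 5, peak_velocity_dps = abs(A),
                   onset_ms = 213 + lat, onset_latency_ms = lat,
                   seq_index = NA_integer_, timing_class = NA_character_,
                   direction_class = NA_character_, J = 0, residual_rms = 0,
                   converged = TRUE, n_iter = 1), class = "saccade_fit")
  }
  fits <- list(mk_fit(-200, 40, 280),   # too early -> dropped
               mk_fit(-200, 80, 320),   # compensatory covert
               mk_fit(+150, 120, 360),  # anti-compensatory -> no seq index
               mk_fit(-100, 200, 440))  # compensatory overt
  out <- classify_saccades(fits, imp, fit_config())
  expect_length(out, 3)
  expect_identical(out[[1]]$direction_class, "compensatory")
  expect_identical(out[[1]]$timing_class, "covert")
  expect_identical(out[[1]]$seq_index, 1L)
  expect_identical(out[[2]]$direction_class, "anti_compensatory")
  expect_true(is.na(out[[2]]$seq_index))
  expect_identical(out[[3]]$timing_class, "overt")
  expect_identical(out[[3]]$seq_index, 2L)
})

test_that("false-positive saccade rate stays below 2% on saccade-free noisy trials", {
  cfg <- synth_config(n_trials = 60, vor_gain = c(0.93, 0.03),
                      saccades = list(), noise_sd_dps = 3)
  batch <- generate_batch(cfg, seed = 19)
  res <- analyze_batch_quiet(batch$traces)
  n_fp <- sum(vapply(res$records, function(r)
    length(Filter(function(f) identical(f$direction_class, "compensatory"),
                  r$saccades)) > 0, logical(1)))
  expect_lte(n_fp / max(length(res$records), 1), 0.02)
})

test_that("parameter recovery stays accurate over a randomized regime sweep", {
  set.seed(23)
  n <- 30
  amp_err <- lat_err <- numeric(0)
  for (i in seq_len(n)) {
    amp <- runif(1, 2, 8); sg <- runif(1, 8, 20); lat <- runif(1, 100, 350)
    tri <- make_trial(gain = runif(1, 0.1, 0.6), noise = 3,
                      vp = runif(1, 150, 250), dur = runif(1, 130, 180),
                      saccades = list(list(amp = amp, lat = lat, sigma = sg)),
                      id = sprintf("sweep_%d", i))
    imp <- tryCatch(detect_impulse(tri$trace),
                    vorsac_rejected = function(e) NULL)
    if (is.null(imp)) next
    fits <- Filter(function(f) identical(f$seq_index, 1L),
                   fit_saccades(tri$trace, imp, fit_config()))
    if (!length(fits)) next
    amp_err <- c(amp_err, abs(abs(fits[[1]]$amplitude_deg) - amp) / amp)
    lat_err <- c(lat_err, abs(fits[[1]]$onset_latency_ms - lat))
  }
  expect_gt(length(amp_err), 0.8 * n)
  expect_lt(stats::median(amp_err), 0.05)
  expect_lt(stats::median(lat_err), 8)
})
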