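test_that("noiseless generator/analyzer round trip is exact", {
  for (s in 1:4) {
    rec <- generate_trace(preset$schedule, preset$params, 60, 0.01, 0,
                          seed = s)
    a <- analyze_trace(rec$trace)
    expect_identical(nrow(a$events), length(rec$truth$event_times))
    expect_lt(max(abs(a$events$amplitude / rec$truth$peak_force_un - 1)),
              0.01)
  }
})

test_that("degenerate traces: flat gives zero peaks, short is an error", {
  flat <- contraction_trace(seq(0, 10, 0.01), rep(3, 1001), "uN")
  expect_identical(nrow(detect_peaks(flat)), 0L)
  short <- contraction_trace(seq(0, 2, 0.01), rnorm(201), "uN")
  expect_error(detect_peaks(short), "5 s")
})

test_that("detection at 5% amplitude noise: >=95% recall, no false peaks", {
  recall <- numeric(10); fp <- numeric(10)
  for (s in 1:10) {
    rec <- generate_trace(preset$schedule, preset$params, 60, 0.01,
                          noise_sd_un = 0.05 * 61, seed = s)
    pk <- detect_peaks(rec$trace)
    m <- match_events(pk$time_s, rec$truth$event_times,
                      tol = 2 * preset$params$time_to_peak)
    recall[s] <- m$recall; fp[s] <- m$false_pos
  }
  expect_gte(mean(recall), 0.95)
  expect_identical(sum(fp), 0)
})

test_that("single-twitch measurement matches the generator ground truth", {
  tr <- single_twitch_trace(twitch_params(61, 0.2, 0.3))
  a <- analyze_trace(tr)
  expect_identical(a$summary$n_twitches, 1L)
  expect_lt(abs(a$events$amplitude / 61 - 1), 0.01)
  expect_false(a$summary$frequency_defined)
  expect_true(is.na(a$summary$frequency_hz))
})

test_that("symmetric waveforms give equal contraction/relaxation slopes", {
  sym <- twitch_params(61, 0.25, 0.25)
  rec <- generate_trace(preset$schedule, sym, 60, 0.01, 0, seed = 4)
  a <- analyze_trace(rec$trace)
  expect_lt(abs(a$summary$mean_contraction_velocity /
                  a$summary$mean_relaxation_velocity - 1), 0.01)
})

test_that("slope estimates match a dense finite-difference oracle", {
  # noiseless single twitch, dense grid, near-disabled smoothing: the
  # estimator must agree with brute-force first differences within 1%
  p <- twitch_params(61, 0.2, 0.3)
  tr <- single_twitch_trace(p, dt = 0.001)
  a <- analyze_trace(tr, cfg = detection_settings(smooth_window_s = 0.005))
  dt <- 0.001
  oracle_up <- max(diff(tr$value)) / dt
  oracle_down <- max(-diff(tr$value)) / dt
  expect_lt(abs(a$events$max_contraction_slope / oracle_up - 1), 0.01)
  expect_lt(abs(a$events$max_relaxation_slope / oracle_down - 1), 0.01)
})

test_that("drug-slowed relaxation is recovered at the model scale factor", {
  cp <- eht_compound_preset("e4031_like")
  st <- apply_drug_effect(preset$params, preset$schedule, cp$model, 100)
  a0 <- analyze_trace(generate_trace(preset$schedule, preset$params, 60,
                                     0.01, 0, seed = 11)$trace)
  a1 <- analyze_trace(generate_trace(st$schedule, st$params, 60,
                                     0.01, 0, seed = 11)$trace)
  measured <- a1$summary$mean_relaxation_velocity /
    a0$summary$mean_relaxation_velocity
  predicted <- relax_scale(cp$model, 100) * force_scale(cp$model, 100)
  expect_lt(abs(measured / predicted - 1), 0.03)
})

test_that("recording summary arithmetic", {
  ev <- data.frame(peak_time = seq(1, 59, 2), amplitude = 61,
                   max_contraction_slope = 400, max_relaxation_slope = 300,
                   contraction_time = 0.2, relaxation_time = 0.3)
  s <- summarize_recording(ev, 60)
  expect_identical(s$n_twitches, 30L)
  expect_equal(s$frequency_hz, 0.5)
  expect_equal(s$frequency_bpm, 30)
  expect_equal(s$mean_force_un, 61)
  empty <- summarize_recording(ev[0, ], 60)
  expect_identical(empty$n_twitches, 0L)
  expect_true(is.na(empty$mean_force_un))
  expect_false(empty$frequency_defined)
})

test_that("mean force over 4 seeds reproduces the 61 uN preset", {
  mf <- vapply(1:4, function(s) {
    analyze_trace(generate_trace(preset$schedule, preset$params, 60, 0.01,
                                 0.5, seed = s)$trace)$summary$mean_force_un
  }, numeric(1))
  expect_lt(abs(mean(mf) / 61 - 1), 0.05)
})

test_that("amplitude/slope estimates: offset and scale invariance", {
  rec <- generate_trace(preset$schedule, preset$params, 60, 0.01, 0.5,
                        seed = 6)
  base <- analyze_trace(rec$trace)$summary
  shift <- contraction_trace(rec$trace$time_s, rec$trace$value + 25, "uN")
  s1 <- analyze_trace(shift)$summary
  expect_equal(s1$mean_force_un, base$mean_force_un, tolerance = 1e-10)
  expect_equal(s1$mean_relaxation_velocity, base$mean_relaxation_velocity,
               tolerance = 1e-10)
  expect_equal(s1$frequency_hz, base$frequency_hz, tolerance = 1e-12)
  scaled <- contraction_trace(rec$trace$time_s, rec$trace$value * 3, "uN")
  s2 <- analyze_trace(scaled)$summary
  expect_equal(s2$mean_force_un, 3 * base$mean_force_un, tolerance = 1e-10)
  expect_equal(s2$mean_contraction_velocity,
               3 * base$mean_contraction_velocity, tolerance = 1e-10)
  expect_equal(s2$frequency_hz, base$frequency_hz, tolerance = 1e-12)
})

test_that("2x downsampling moves amplitudes <1% and slopes <5%", {
  rec <- generate_trace(preset$schedule, preset$params, 60, 0.01, 0,
                        seed = 3)
  half <- contraction_trace(rec$trace$time_s[c(TRUE, FALSE)],
                            rec$trace$value[c(TRUE, FALSE)], "uN")
  a <- analyze_trace(rec$trace)$summary
  b <- analyze_trace(half)$summary
  expect_lt(abs(b$mean_force_un / a$mean_force_un - 1), 0.01)
  expect_lt(abs(b$mean_relaxation_velocity / a$mean_relaxation_velocity - 1),
            0.05)
  expect_lt(abs(b$mean_contraction_velocity / a$mean_contraction_velocity - 1),
            0.05)
})
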