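test_that("twitch waveform has the stated shape", {
  p <- twitch_params(61, 0.2, 0.3, diastolic_force_un = 2)
  wf <- generate_twitch_waveform(p, 0.001)
  expect_equal(max(wf$value), 2 + 61, tolerance = 0.005)
  expect_lt(abs(wf$value[1] - 2), 0.01 * 61)
  expect_lt(abs(wf$value[nrow(wf)] - 2), 0.01 * 61)
  # single maximum, continuous first difference (no slope jumps beyond
  # what the C1 template curvature allows)
  dv <- diff(wf$value)
  expect_equal(sum(diff(sign(dv[dv != 0])) != 0), 1)
  # second difference bounded by the template curvature: a slope kink
  # would blow this up by ~1/dt
  expect_lt(max(abs(diff(dv))) / 0.001^2, 61 / 2 * (pi / 0.2)^2 * 2.5)

  flat <- generate_twitch_waveform(twitch_params(0, 0.2, 0.3, 5), 0.001)
  expect_true(all(flat$value == 5))
  expect_error(generate_twitch_waveform(p, 0.05), "dt")
  expect_error(generate_twitch_waveform(p, -1), "dt")
})

test_that("doubling peak force doubles the maximal upstroke slope", {
  # finite-difference slope oracle on the rendered waveform
  dt <- 1e-4
  s1 <- max(diff(generate_twitch_waveform(twitch_params(61), dt)$value)) / dt
  s2 <- max(diff(generate_twitch_waveform(twitch_params(122), dt)$value)) / dt
  expect_equal(s2 / s1, 2, tolerance = 1e-9)
  # and both match the analytic maximum A*pi/(2*ttp)
  expect_equal(s1, 61 * pi / (2 * 0.2), tolerance = 1e-4)
})

test_that("generate_trace: event count, determinism, noise level", {
  rec <- generate_trace(preset$schedule, preset$params, 60, 0.01, 0.5,
                        seed = 1)
  expect_true(abs(length(rec$truth$event_times) - 30) <= 1)
  expect_true(all(diff(rec$truth$event_times) > 0))
  rec2 <- generate_trace(preset$schedule, preset$params, 60, 0.01, 0.5,
                         seed = 1)
  expect_identical(rec$trace$value, rec2$trace$value)  # bit-identical

  # identical seed, noise off: the residual is exactly the additive noise
  clean <- generate_trace(preset$schedule, preset$params, 60, 0.01, 0,
                          seed = 1)
  resid <- rec$trace$value - clean$trace$value
  expect_equal(sd(resid), 0.5, tolerance = 0.05)
  expect_equal(mean(resid), 0, tolerance = 0.02)

  # degenerate schedule: all intervals equal to the period
  reg <- generate_trace(beat_schedule(0.5, 0), preset$params, 60, 0.01, 0,
                        seed = 3)
  expect_equal(unique(round(diff(reg$truth$event_times), 12)), 2)
})

test_that("overlapping twitches are flagged but still recorded", {
  fast <- beat_schedule(4, 0)  # 0.25 s period < 0.5 s twitch duration
  rec <- generate_trace(fast, preset$params, 10, 0.01, 0, seed = 1)
  expect_true(rec$truth$overlap)
  expect_gt(length(rec$truth$event_times), 30)
})

test_that("calcium model satisfies both printed constraints and monotony", {
  m <- calcium_response_model()
  expect_equal(calcium_scale(0.2, m) / calcium_scale(1.8, m), 0.10,
               tolerance = 1e-9)
  expect_gte(calcium_scale(2.2, m) / calcium_scale(3.0, m), 0.95)
  expect_equal(calcium_scale(1.8, m), 1, tolerance = 1e-12)
  grid <- calcium_scale(seq(0.2, 3.0, by = 0.01), m)
  expect_true(all(diff(grid) >= 0))
  expect_true(all(grid > 0))
  expect_error(calcium_scale(0, m))
})

test_that("drug effect model: identity at zero, Hill midpoint, saturation", {
  m <- drug_effect_model("testdrug", ic50_relax = 10, scatter_onset = 10,
                         max_reduction = 0.4)
  st <- apply_drug_effect(preset$params, preset$schedule, m, 0)
  expect_identical(st$params, preset$params)
  expect_identical(st$schedule, preset$schedule)
  expect_equal(relax_scale(m, 10), 1 - 0.4 / 2)          # Hill midpoint
  expect_equal(relax_scale(m, 1e6), 1 - 0.4, tolerance = 1e-4)
  # maximal effects stay in the reported 30-50% reduction band
  expect_true(relax_scale(m, Inf) >= 0.5 && relax_scale(m, Inf) <= 0.7)
  expect_error(apply_drug_effect(preset$params, preset$schedule, m, -1),
               "conc")
  # monotone: relaxation scale non-increasing, interval cv non-decreasing
  ladder <- c(0, 1, 3, 10, 30, 100, 1000)
  expect_true(all(diff(relax_scale(m, ladder)) <= 0))
  cvs <- vapply(ladder, function(cc) {
    apply_drug_effect(preset$params, preset$schedule, m, cc)$schedule$interval_cv
  }, numeric(1))
  expect_true(all(diff(cvs) >= 0))
})

test_that("chronotropy: isoprenaline raises frequency, carbachol reverses", {
  cm <- chronotropy_model(isoprenaline_freq_gain = 1.3)
  iso <- apply_chronotropy(preset$schedule, cm, isoprenaline = TRUE)
  rev <- apply_chronotropy(preset$schedule, cm, isoprenaline = TRUE,
                           carbachol = TRUE)
  f <- function(s, seed) {
    analyze_trace(generate_trace(s, preset$params, 60, 0.01, 0.5,
                                 seed = seed)$trace)$summary$frequency_hz
  }
  f0 <- f(preset$schedule, 1); fi <- f(iso, 1); fr <- f(rev, 1)
  expect_gt(fi, f0 * 1.1)
  expect_lt(abs(fr / f0 - 1), 0.05)
})
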