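cam0 <- camera_model()  # noiseless default

test_that("zero deflection renders a constant marker separation", {
  tr <- contraction_trace(seq(0, 1, 0.02), rep(0, 51), unit = "um")
  stk <- render_frames(tr, cam0)
  seps <- vapply(stk$frames, function(fr) {
    d <- detect_markers(fr)
    diff(d$centroids[, "y"])
  }, numeric(1))
  expect_equal(max(seps) - min(seps), 0, tolerance = 1e-9)
  tracked <- track_deflection(stk)
  expect_equal(max(abs(tracked$value)), 0, tolerance = 1e-9)
})

test_that("a 100 um step at 20 px/mm moves the separation by 2 px", {
  tr <- contraction_trace(seq(0, 1, 0.02), rep(c(0, 100), each = 26)[1:51],
                          unit = "um")
  cam <- camera_model(pixels_per_mm = 20, frame_height = 320)
  stk <- render_frames(tr, cam)
  sep <- function(i) diff(detect_markers(stk$frames[[i]])$centroids[, "y"])
  expect_equal(sep(1) - sep(51), 2, tolerance = 1e-6)
})

test_that("marker centroids: exactness, failure flag, noise robustness", {
  tr <- contraction_trace(seq(0, 1, 0.02), seq(0, 400, length.out = 51),
                          unit = "um")
  stk <- render_frames(tr, cam0)
  for (i in c(1, 25, 51)) {
    d <- detect_markers(stk$frames[[i]])
    expect_true(d$ok)
    expect_lt(max(abs(d$centroids[, "y"] - stk$truth_centers_px[i, ])), 0.1)
  }
  expect_false(detect_markers(matrix(0.5, 40, 20))$ok)

  # 5% of contrast noise: sub-0.3 px error on >=95% of frames and an
  # (almost) unbiased estimator
  camn <- camera_model(noise_sd = 0.05 * 0.6)
  stkn <- render_frames(tr, camn, seed = 99)
  errs <- signed <- rep(NA_real_, 51)
  for (i in 1:51) {
    d <- detect_markers(stkn$frames[[i]])
    if (!d$ok) next
    delta <- d$centroids[, "y"] - stkn$truth_centers_px[i, ]
    errs[i] <- max(abs(delta))
    signed[i] <- mean(delta)
  }
  expect_gte(mean(errs < 0.3, na.rm = TRUE), 0.95)
  expect_lt(abs(mean(signed, na.rm = TRUE)), 0.05)
})

test_that("tracking is invariant to the pixel scale", {
  tr <- contraction_trace(seq(0, 1, 0.02),
                          200 * (1 - cos(2 * pi * seq(0, 1, 0.02))) / 2,
                          unit = "um")
  d1 <- track_deflection(render_frames(tr, camera_model(pixels_per_mm = 10)))
  d2 <- track_deflection(render_frames(tr, camera_model(pixels_per_mm = 20,
                                                        frame_height = 320)))
  expect_equal(d1$value, d2$value, tolerance = 1e-6)
})

test_that("markers leaving the frame abort the render", {
  tr <- contraction_trace(seq(0, 1, 0.02), rep(0, 51), unit = "um")
  expect_error(render_frames(tr, cam0, rest_separation_mm = 17),
               "frame")
})

test_that("noiseless tracking recovers the deflection to <0.5 px equiv", {
  rec <- generate_trace(preset$schedule, preset$params, 10, 0.02, 0,
                        seed = 5)
  defl <- trace_to_deflection(rec$trace, geom)
  stk <- render_frames(defl, cam0)
  tracked <- track_deflection(stk)
  px_um <- 1000 / cam0$pixels_per_mm
  expect_lt(max(abs(tracked$value - defl$value)), 0.5 * px_um)
})

test_that("excessive lost frames raise a tracking error, few are bridged", {
  rec <- generate_trace(preset$schedule, preset$params, 10, 0.02, 0,
                        seed = 5)
  stk <- render_frames(trace_to_deflection(rec$trace, geom), cam0)
  bad <- stk
  bad$frames[seq(1, 301, by = 10)] <-  # 31 of 501 frames > 5%
    replicate(31, matrix(0.8, cam0$frame_height, cam0$frame_width),
              simplify = FALSE)
  expect_error(track_deflection(bad), "lost")
  ok <- stk
  ok$frames[c(40, 240)] <-
    replicate(2, matrix(0.8, cam0$frame_height, cam0$frame_width),
              simplify = FALSE)
  tracked <- track_deflection(ok)
  expect_identical(attr(tracked, "lost_frames"), 2L)
  expect_identical(nrow(tracked), length(stk$timestamps))
})

test_that("video path agrees with the direct-trace path (noiseless)", {
  rec <- generate_trace(preset$schedule, preset$params, 20, 0.02, 0,
                        seed = 5)
  defl <- trace_to_deflection(rec$trace, geom)
  direct <- analyze_trace(trace_to_force(defl, geom))$summary
  video <- analyze_trace(trace_to_force(track_deflection(
    render_frames(defl, cam0)), geom))$summary
  expect_identical(video$n_twitches, direct$n_twitches)
  for (f in c("mean_force_un", "frequency_hz", "mean_contraction_velocity",
              "mean_relaxation_velocity", "mean_contraction_time",
              "mean_relaxation_time")) {
    expect_lt(abs(video[[f]] / direct[[f]] - 1), 0.05)
  }
})
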