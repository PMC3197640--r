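#' Beat schedule
#'
#' Statistical description of the spontaneous beating rhythm. Intervals
#' between beats are drawn lognormal with mean `1/base_frequency_hz` and
#' coefficient of variation `interval_cv` (strictly positive by
#' construction). In `"scattered"` mode -- the phenotype induced by
#' proarrhythmic compounds -- occasional skipped beats (doubled interval)
#' and early beats (halved interval) are superimposed on the inflated cv.
#'
#' @param base_frequency_hz mean spontaneous frequency, Hz (default 0.5 Hz,
#'   the reported population mean; individual tissues range 40-70 bpm).
#' @param interval_cv coefficient of variation of beat intervals; >= 0.
#'   Default 0.05: regular beating with mild physiological jitter.
#' @param irregularity_mode `"regular"` or `"scattered"`.
#' @return object of class `beat_schedule`.
#' @export
beat_schedule <- function(base_frequency_hz = 0.5,
                          interval_cv = 0.05,
                          irregularity_mode = c("regular", "scattered")) {
  irregularity_mode <- match.arg(irregularity_mode)
  if (!is_scalar_num(base_frequency_hz) || base_frequency_hz <= 0) {
    stop_param("base_frequency_hz must be > 0")
  }
  if (!is_scalar_num(interval_cv) || interval_cv < 0) {
    stop_param("interval_cv must be >= 0")
  }
  structure(
    list(base_frequency = base_frequency_hz,
         interval_cv = interval_cv,
         irregularity_mode = irregularity_mode),
    class = "beat_schedule"
  )
}

# Draw n beat-to-beat intervals under the schedule. Lognormal parameters are
# chosen so the intervals have mean 1/f and cv = interval_cv exactly.
draw_intervals <- function(schedule, n) {
  m <- 1 / schedule$base_frequency
  cv <- schedule$interval_cv
  if (cv == 0) {
    iv <- rep(m, n)
  } else {
    s2 <- log(1 + cv^2)
    iv <- stats::rlnorm(n, meanlog = log(m) - s2 / 2, sdlog = sqrt(s2))
  }
  if (schedule$irregularity_mode == "scattered") {
    u <- stats::runif(n)
    iv[u < 0.10] <- iv[u < 0.10] * 2            # skipped beat
    early <- u >= 0.10 & u < 0.20
    iv[early] <- iv[early] * 0.5                # premature beat
  }
  iv
}

#' Generate a synthetic contraction recording
#'
#' Renders a force trace of spontaneously beating EHT: twitches from
#' [generate_twitch_waveform()] placed at lognormally jittered onsets, plus
#' additive Gaussian measurement noise. All randomness derives from `seed`;
#' identical arguments give bit-identical traces. If any beat interval is
#' shorter than one twitch duration the overlapping waveforms are summed and
#' the ground truth carries an `overlap` flag.
#'
#' @param schedule a [beat_schedule()].
#' @param params a [twitch_params()].
#' @param duration_s recording length, s (default 60 s, the standard
#'   measurement window).
#' @param dt sample interval, s (default 0.01 s; 100 Hz video rate).
#' @param noise_sd_un sd of additive Gaussian noise, uN. Default 0.5 uN,
#'   the force equivalent of ~0.1 px centroid precision through an
#'   illustrative 0.15 N/mm-stiffness post.
#' @param seed integer seed fixing all randomness.
#' @param well_id label attached to the trace.
#' @return list with `trace` (a [contraction_trace()], uN) and `truth`
#'   (class `ground_truth`: `event_times` = peak times s, `peak_force_un`
#'   per event, `onset_times`, `overlap` flag, condition descriptors).
#' @export
generate_trace <- function(schedule, params, duration_s = 60, dt = 0.01,
                           noise_sd_un = 0.5, seed = 1L,
                           well_id = "synthetic") {
  stopifnot(inherits(schedule, "beat_schedule"),
            inherits(params, "twitch_params"))
  if (!is_scalar_num(duration_s) || duration_s <= 0) {
    stop_param("duration_s must be > 0")
  }
  if (!is_scalar_num(noise_sd_un) || noise_sd_un < 0) {
    stop_param("noise_sd_un must be >= 0")
  }
  twitch_len <- params$time_to_peak + params$relaxation_time
  with_seed(seed, {
    n_draw <- ceiling(duration_s * schedule$base_frequency * 2) + 10L
    iv <- draw_intervals(schedule, n_draw)
    # first onset at half an interval so a 60 s / 0.5 Hz recording holds
    # its nominal 30 full twitches
    onsets <- cumsum(c(iv[1] / 2, iv[-1]))
    onsets <- onsets[onsets + twitch_len <= duration_s]
    t <- seq(0, duration_s, by = dt)
    value <- rep(params$diastolic_force, length(t))
    for (on in onsets) {
      idx <- which(t >= on & t <= on + twitch_len)
      value[idx] <- value[idx] + twitch_template(t[idx] - on, params)
    }
    if (noise_sd_un > 0) value <- value + stats::rnorm(length(t), 0, noise_sd_un)

    overlap <- length(onsets) > 1 && any(diff(onsets) < twitch_len)
    truth <- structure(
      list(event_times = onsets + params$time_to_peak,
           peak_force_un = rep(params$peak_force, length(onsets)),
           onset_times = onsets,
           overlap = overlap,
           condition = list(schedule = schedule, params = params,
                            noise_sd_un = noise_sd_un, seed = seed)),
      class = "ground_truth"
    )
    list(trace = contraction_trace(t, value, unit = "uN", well_id = well_id),
         truth = truth)
  })
}
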