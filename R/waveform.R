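#' Twitch parameters
#'
#' Parameters of one contraction twitch of a spontaneously beating EHT.
#' Defaults describe the spontaneous human-EHT preset: 61 uN peak force
#' (population mean 0.061 mN), 0.2 s to peak, 0.3 s relaxation, zero
#' diastolic offset (forces are reported relative to the resting posts).
#'
#' @param peak_force_un twitch amplitude above diastole, uN; > 0 (0 allowed
#'   for a degenerate flat twitch).
#' @param time_to_peak_s time from contraction onset to peak, s.
#' @param relaxation_time_s time from peak back to diastole, s.
#' @param diastolic_force_un resting force offset, uN, >= 0.
#' @return object of class `twitch_params`.
#' @export
twitch_params <- function(peak_force_un = 61,
                          time_to_peak_s = 0.2,
                          relaxation_time_s = 0.3,
                          diastolic_force_un = 0) {
  if (!is_scalar_num(peak_force_un) || peak_force_un < 0) {
    stop_param("peak_force_un must be a non-negative number (uN)")
  }
  if (!is_scalar_num(time_to_peak_s) || time_to_peak_s <= 0) {
    stop_param("time_to_peak_s must be > 0")
  }
  if (!is_scalar_num(relaxation_time_s) || relaxation_time_s <= 0) {
    stop_param("relaxation_time_s must be > 0")
  }
  if (!is_scalar_num(diastolic_force_un) || diastolic_force_un < 0) {
    stop_param("diastolic_force_un must be >= 0")
  }
  structure(
    list(peak_force = peak_force_un,
         time_to_peak = time_to_peak_s,
         relaxation_time = relaxation_time_s,
         diastolic_force = diastolic_force_un),
    class = "twitch_params"
  )
}

# Two-phase raised-cosine twitch template evaluated at times `t` (s) after
# contraction onset. C1-smooth: zero slope at onset, peak and end, single
# maximum of exactly `peak_force` above diastole, analytic maximal slopes
# A*pi/(2*ttp) (rise) and A*pi/(2*trel) (fall) -- used as slope oracles.
twitch_template <- function(t, params) {
  ttp <- params$time_to_peak
  trel <- params$relaxation_time
  a <- params$peak_force
  y <- numeric(length(t))
  rise <- t >= 0 & t <= ttp
  fall <- t > ttp & t <= ttp + trel
  y[rise] <- a / 2 * (1 - cos(pi * t[rise] / ttp))
  y[fall] <- a / 2 * (1 + cos(pi * (t[fall] - ttp) / trel))
  y
}

#' Render one twitch waveform
#'
#' Samples a single contraction twitch on a uniform grid. The waveform is a
#' smooth two-phase raised-cosine: a rising limb of length `time_to_peak`
#' and a falling limb of length `relaxation_time`, starting and ending at
#' the diastolic force with zero slope, with a single maximum of
#' `diastolic + peak_force`. Maximal slopes are analytic
#' (`peak_force * pi / (2 * time_to_peak)` on the rise), which makes
#' downstream slope estimators testable against a closed form.
#'
#' @param params a [twitch_params()].
#' @param dt sample interval, s; must satisfy `dt <= time_to_peak / 10`.
#' @return data.frame with columns `time_s`, `value` (uN).
#' @export
generate_twitch_waveform <- function(params, dt) {
  stopifnot(inherits(params, "twitch_params"))
  if (!is_scalar_num(dt) || dt <= 0 || dt > params$time_to_peak / 10) {
    stop_param("dt must be positive and <= time_to_peak / 10")
  }
  t <- seq(0, params$time_to_peak + params$relaxation_time, by = dt)
  data.frame(time_s = t,
             value = params$diastolic_force + twitch_template(t, params))
}
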