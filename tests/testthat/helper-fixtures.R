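# shared fixtures: the spontaneous-beating preset and illustrative geometry
preset <- eht_preset("spontaneous_heht")
geom <- default_post_geometry()

# a single noiseless twitch embedded in a quiet 6 s trace
single_twitch_trace <- function(params = twitch_params(), dt = 0.001,
                                onset = 3) {
  t <- seq(0, 6, by = dt)
  y <- rep(params$diastolic_force, length(t))
  wf <- generate_twitch_waveform(params, dt)
  idx <- which(t >= onset &
                 t <= onset + params$time_to_peak + params$relaxation_time)
  y[idx] <- wf$value[seq_along(idx)]
  contraction_trace(t, y, unit = "uN")
}

# fraction of ground-truth events matched by detected peak times
match_events <- function(detected_times, truth_times, tol) {
  hits <- vapply(truth_times, function(tt) {
    any(abs(detected_times - tt) <= tol)
  }, logical(1))
  list(recall = mean(hits),
       false_pos = sum(vapply(detected_times, function(dt) {
         all(abs(truth_times - dt) > tol)
       }, logical(1))))
}
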