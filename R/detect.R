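#' Peak-detection settings
#'
#' Tuning knobs of the automated twitch recognition, with defaults chosen
#' for spontaneous beating at 40-70 bpm with modest noise: 50 ms
#' moving-average smoothing, prominence threshold at 20% of the trace
#' dynamic range, 250 ms refractory interval between accepted peaks.
#'
#' @param smooth_window_s moving-average window, s.
#' @param min_prominence_frac prominence threshold as a fraction of the
#'   smoothed trace's dynamic range.
#' @param min_interval_s minimal separation between accepted peaks, s.
#' @param baseline_frac fractional-amplitude threshold defining the start
#'   and end of a twitch (contraction/relaxation time endpoints).
#' @return list of class `detection_settings`.
#' @export
detection_settings <- function(smooth_window_s = 0.05,
                               min_prominence_frac = 0.2,
                               min_interval_s = 0.25,
                               baseline_frac = 0.1) {
  stopifnot(smooth_window_s > 0, min_prominence_frac > 0,
            min_prominence_frac < 1, min_interval_s >= 0,
            baseline_frac > 0, baseline_frac < 0.5)
  structure(list(smooth_window_s = smooth_window_s,
                 min_prominence_frac = min_prominence_frac,
                 min_interval_s = min_interval_s,
                 baseline_frac = baseline_frac),
            class = "detection_settings")
}

# centred moving average with shrinking edge windows
moving_average <- function(x, w) {
  w <- as.integer(w)
  if (w <= 1L) return(x)
  n <- length(x)
  half <- (w - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

smooth_trace_values <- function(trace, cfg) {
  w <- round(cfg$smooth_window_s * trace_rate(trace))
  if (w %% 2 == 0) w <- w + 1
  moving_average(trace$value, w)
}

# topographic prominence of local maximum at index i of signal s
peak_prominence <- function(s, i) {
  n <- length(s)
  left_higher <- which(s[seq_len(i - 1)] > s[i])
  lo <- if (length(left_higher)) max(left_higher) + 1L else 1L
  min_l <- min(s[lo:i])
  right_higher <- which(s[(i + 1):n] > s[i])
  hi <- if (i < n && length(right_higher)) i + min(right_higher) - 1L else n
  min_r <- min(s[i:hi])
  s[i] - max(min_l, min_r)
}

#' Detect contraction peaks
#'
#' Automated twitch recognition: the trace is smoothed by a centred moving
#' average, local maxima are ranked by topographic prominence, maxima whose
#' prominence exceeds `min_prominence_frac` of the smoothed dynamic range
#' are kept, and a refractory rule enforces at least `min_interval_s`
#' between accepted peaks (keeping the more prominent one). Fully
#' deterministic. A flat trace yields zero peaks, not an error.
#'
#' @param trace a [contraction_trace()] of at least 5 s.
#' @param cfg a [detection_settings()].
#' @return data.frame of class `peak_list` with columns `index`, `time_s`,
#'   `value` (raw trace value at the peak sample), ordered by time.
#' @export
detect_peaks <- function(trace, cfg = detection_settings()) {
  stopifnot(inherits(trace, "contraction_trace"))
  span <- trace$time_s[nrow(trace)] - trace$time_s[1]
  if (span < cfg$smooth_window_s) {
    stop_param("trace shorter than the smoothing window")
  }
  if (span < 5) stop_param("trace must cover at least 5 s")
  s <- smooth_trace_values(trace, cfg)
  empty <- data.frame(index = integer(), time_s = numeric(),
                      value = numeric())
  class(empty) <- c("peak_list", "data.frame")
  rng <- max(s) - min(s)
  if (rng == 0) return(empty)
  n <- length(s)
  cand <- which(s[-c(1, n)] > s[-c(n - 1, n)] &
                  s[-c(1, n)] >= s[-c(1, 2)]) + 1L
  if (!length(cand)) return(empty)
  thr <- cfg$min_prominence_frac * rng
  # prominence never exceeds height above the global minimum: cheap prefilter
  cand <- cand[s[cand] - min(s) >= thr]
  if (!length(cand)) return(empty)
  prom <- vapply(cand, function(i) peak_prominence(s, i), numeric(1))
  keep <- prom >= thr
  cand <- cand[keep]
  prom <- prom[keep]
  if (!length(cand)) return(empty)
  # refractory rule: visit by decreasing prominence, drop peaks within
  # min_interval_s of an already-accepted, more prominent peak
  ord <- order(prom, s[cand], decreasing = TRUE)
  accepted <- integer()
  for (i in cand[ord]) {
    if (!length(accepted) ||
        all(abs(trace$time_s[accepted] - trace$time_s[i]) >= cfg$min_interval_s)) {
      accepted <- c(accepted, i)
    }
  }
  accepted <- sort(accepted)
  out <- data.frame(index = accepted, time_s = trace$time_s[accepted],
                    value = trace$value[accepted])
  class(out) <- c("peak_list", "data.frame")
  out
}

#' Measure twitch parameters at detected peaks
#'
#' For each detected peak the diastolic baseline is estimated as the mean of
#' the smoothed-signal minima in the two adjacent inter-beat windows
#' (bounded by the neighbouring peaks, or the trace ends). Amplitude is the
#' smoothed peak value minus that baseline. Contraction and relaxation
#' times run from/to the `baseline_frac` (default 10%) amplitude crossing;
#' maximal contraction and relaxation velocities are the extreme first
#' differences of the smoothed signal on the rising and falling limbs
#' (relaxation reported positive). Twitches whose limb never returns to the
#' 10% level inside the available window -- typically truncated boundary
#' twitches -- are dropped: only "measurable" twitches are reported.
#'
#' @param trace a [contraction_trace()].
#' @param peaks a `peak_list` from [detect_peaks()] on the same trace.
#' @param cfg the same [detection_settings()] used for detection.
#' @return data.frame of class `twitch_events` with columns `peak_time`,
#'   `amplitude`, `max_contraction_slope`, `max_relaxation_slope`
#'   (positive), `contraction_time`, `relaxation_time`. Units follow the
#'   trace unit (uN and uN/s for force traces). Empty with attribute
#'   `diagnostic` if nothing is measurable.
#' @export
measure_twitches <- function(trace, peaks, cfg = detection_settings()) {
  stopifnot(inherits(trace, "contraction_trace"), is.data.frame(peaks))
  empty <- data.frame(peak_time = numeric(), amplitude = numeric(),
                      max_contraction_slope = numeric(),
                      max_relaxation_slope = numeric(),
                      contraction_time = numeric(),
                      relaxation_time = numeric())
  class(empty) <- c("twitch_events", "data.frame")
  if (!nrow(peaks)) {
    attr(empty, "diagnostic") <- "no peaks supplied"
    return(empty)
  }
  s <- smooth_trace_values(trace, cfg)
  t <- trace$time_s
  dt <- 1 / trace_rate(trace)
  idx <- peaks$index
  rows <- vector("list", length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    lwin <- if (k > 1) idx[k - 1] else 1L
    rwin <- if (k < length(idx)) idx[k + 1] else length(s)
    left <- s[lwin:i]
    right <- s[i:rwin]
    base_l <- min(left)
    base_r <- min(right)
    baseline <- (base_l + base_r) / 2
    amp <- s[i] - baseline
    if (amp <= 0) next
    thr <- baseline + cfg$baseline_frac * amp
    below_l <- which(left <= thr)
    below_r <- which(right <= thr)
    if (!length(below_l) || !length(below_r)) next  # truncated limb
    j_on <- lwin + max(below_l) - 1L
    j_off <- i + min(below_r) - 1L
    i_min_l <- lwin + which.min(left) - 1L
    i_min_r <- i + which.min(right) - 1L
    up <- if (i > i_min_l) max(diff(s[i_min_l:i])) / dt else NA_real_
    down <- if (i_min_r > i) max(-diff(s[i:i_min_r])) / dt else NA_real_
    if (!is.finite(up) || !is.finite(down) || up <= 0 || down <= 0) next
    rows[[k]] <- data.frame(
      peak_time = t[i], amplitude = amp,
      max_contraction_slope = up, max_relaxation_slope = down,
      contraction_time = t[i] - t[j_on],
      relaxation_time = t[j_off] - t[i])
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    attr(empty, "diagnostic") <- "no measurable twitches"
    return(empty)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("twitch_events", "data.frame")
  out
}

#' Summarise a recording
#'
#' Per-recording averages over all measurable twitches: mean amplitude
#' ("force of contraction"), mean maximal contraction/relaxation velocity,
#' mean contraction/relaxation time, and spontaneous frequency computed as
#' (number of intervals) / (summed interval length). With fewer than two
#' twitches the frequency is flagged undefined (`NA`), never fabricated.
#'
#' @param events a `twitch_events` data.frame from [measure_twitches()].
#' @param duration_s length of the recording window, s.
#' @return list of class `recording_summary`: `n_twitches`,
#'   `mean_force_un`, `frequency_hz`, `frequency_bpm`,
#'   `mean_contraction_velocity`, `mean_relaxation_velocity`,
#'   `mean_contraction_time`, `mean_relaxation_time`, `beat_intervals`,
#'   `frequency_defined`, `duration_s`.
#' @export
summarize_recording <- function(events, duration_s) {
  stopifnot(is.data.frame(events), is_scalar_num(duration_s), duration_s > 0)
  n <- nrow(events)
  intervals <- if (n >= 2) diff(events$peak_time) else numeric()
  freq <- if (length(intervals)) length(intervals) / sum(intervals) else NA_real_
  m <- function(x) if (n > 0) mean(x) else NA_real_
  structure(
    list(n_twitches = n,
         mean_force_un = m(events$amplitude),
         frequency_hz = freq,
         frequency_bpm = freq * 60,
         mean_contraction_velocity = m(events$max_contraction_slope),
         mean_relaxation_velocity = m(events$max_relaxation_slope),
         mean_contraction_time = m(events$contraction_time),
         mean_relaxation_time = m(events$relaxation_time),
         beat_intervals = intervals,
         frequency_defined = length(intervals) > 0,
         duration_s = duration_s),
    class = "recording_summary"
  )
}

#' @export
print.recording_summary <- function(x, ...) {
  cat(sprintf("Recording summary (%.4g s): %d twitches\n", x$duration_s,
              x$n_twitches))
  if (x$n_twitches > 0) {
    cat(sprintf("  mean force          %8.3f uN\n", x$mean_force_un))
    if (x$frequency_defined) {
      cat(sprintf("  frequency           %8.3f Hz (%.1f bpm)\n",
                  x$frequency_hz, x$frequency_bpm))
    } else {
      cat("  frequency           undefined (<2 twitches)\n")
    }
    cat(sprintf("  contraction velocity%8.3f uN/s\n",
                x$mean_contraction_velocity))
    cat(sprintf("  relaxation velocity %8.3f uN/s\n",
                x$mean_relaxation_velocity))
  }
  invisible(x)
}

#' Run the whole per-recording analysis chain
#'
#' Convenience wrapper: optional deflection-to-force conversion through the
#' post mechanics, peak detection, twitch measurement and summary.
#'
#' @param trace a [contraction_trace()] in uN, or in um if `geom` is given.
#' @param geom a [post_geometry()], required for deflection traces.
#' @param cfg a [detection_settings()].
#' @return list with `summary` ([summarize_recording()] result), `events`,
#'   `peaks` and the force `trace` analysed.
#' @export
analyze_trace <- function(trace, geom = NULL, cfg = detection_settings()) {
  stopifnot(inherits(trace, "contraction_trace"))
  if (trace_unit(trace) == "um") {
    if (is.null(geom)) {
      stop_param("deflection trace needs a post_geometry to convert to force")
    }
    trace <- trace_to_force(trace, geom)
  }
  peaks <- detect_peaks(trace, cfg)
  events <- measure_twitches(trace, peaks, cfg)
  span <- trace$time_s[nrow(trace)] - trace$time_s[1]
  list(summary = summarize_recording(events, span),
       events = events, peaks = peaks, trace = trace)
}
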