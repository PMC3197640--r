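#' Summarise one recording for dose-response bookkeeping
#'
#' Runs [analyze_trace()] and flattens the result into the single row used
#' by [dose_response_experiment()] (including the per-recording interval
#' IDR, `NA` when fewer than two intervals are available).
#'
#' @param trace a [contraction_trace()].
#' @param well_id,condition,conc labels for the row.
#' @param geom,cfg passed to [analyze_trace()].
#' @return one-row data.frame.
#' @export
summarize_well <- function(trace, well_id, condition, conc = NA_real_,
                           geom = NULL, cfg = detection_settings()) {
  s <- analyze_trace(trace, geom, cfg)$summary
  idr <- if (length(s$beat_intervals) >= 2) {
    interdecile_range(s$beat_intervals)$idr
  } else NA_real_
  data.frame(well_id = well_id, condition = condition, conc = conc,
             n_twitches = s$n_twitches,
             mean_force_un = s$mean_force_un,
             frequency_hz = s$frequency_hz,
             mean_contraction_velocity = s$mean_contraction_velocity,
             mean_relaxation_velocity = s$mean_relaxation_velocity,
             idr = idr)
}

#' Simulate a full cumulative dose-response experiment
#'
#' Generates baseline plus one recording per ladder concentration for each
#' replicate well, with per-well biological variability (twitch force
#' log-normal around the preset with cv `well_force_cv`; spontaneous
#' frequency uniform over `freq_range_bpm`), applies the drug model via
#' [apply_drug_effect()], analyses every recording through the full
#' pipeline and assembles a [dose_response_experiment()]. All randomness
#' derives from `seed`.
#'
#' @param model a [drug_effect_model()].
#' @param ladder strictly increasing concentration ladder.
#' @param n_wells replicate wells (4 in the screening protocol).
#' @param params,schedule presets for the untreated tissue.
#' @param duration_s,dt,noise_sd_un recording parameters, see
#'   [generate_trace()].
#' @param well_force_cv between-well cv of twitch force (0.2 reproduces the
#'   reported 0.061 +/- 0.013 mN spread).
#' @param freq_range_bpm between-well range of spontaneous frequency.
#' @param seed integer seed.
#' @param conc_unit unit label for the ladder.
#' @return a [dose_response_experiment()].
#' @export
simulate_dose_response <- function(model, ladder, n_wells = 4,
                                   params = twitch_params(),
                                   schedule = beat_schedule(),
                                   duration_s = 60, dt = 0.01,
                                   noise_sd_un = 0.5,
                                   well_force_cv = 0.2,
                                   freq_range_bpm = c(40, 70),
                                   seed = 1L, conc_unit = "nM") {
  stopifnot(inherits(model, "drug_effect_model"), n_wells >= 2)
  conds <- c(NA_real_, ladder)  # NA = baseline
  draw <- with_seed(seed, {
    s2 <- log(1 + well_force_cv^2)
    list(force = params$peak_force *
           stats::rlnorm(n_wells, -s2 / 2, sqrt(s2)),
         freq = stats::runif(n_wells, freq_range_bpm[1], freq_range_bpm[2]) / 60,
         seeds = matrix(sample.int(2^30, n_wells * length(conds)),
                        nrow = n_wells))
  })
  rows <- list()
  for (w in seq_len(n_wells)) {
    well_params <- twitch_params(draw$force[w], params$time_to_peak,
                                 params$relaxation_time,
                                 params$diastolic_force)
    well_schedule <- beat_schedule(draw$freq[w], schedule$interval_cv,
                                   schedule$irregularity_mode)
    for (ci in seq_along(conds)) {
      conc <- conds[ci]
      st <- if (is.na(conc)) {
        list(params = well_params, schedule = well_schedule)
      } else {
        apply_drug_effect(well_params, well_schedule, model, conc)
      }
      rec <- generate_trace(st$schedule, st$params, duration_s, dt,
                            noise_sd_un, seed = draw$seeds[w, ci],
                            well_id = sprintf("well%02d", w))
      rows[[length(rows) + 1L]] <- summarize_well(
        rec$trace, sprintf("well%02d", w),
        if (is.na(conc)) "baseline" else as.character(conc), conc)
    }
  }
  dose_response_experiment(model$compound, ladder, do.call(rbind, rows),
                           conc_unit = conc_unit)
}

#' Simulate a calcium concentration-response series
#'
#' Generates recordings at each calcium level for each well, with twitch
#' amplitude scaled by [calcium_scale()] relative to the 1.8 mM baseline
#' medium, and analyses them through the full pipeline.
#'
#' @param ca_levels_mm calcium levels, mM.
#' @param ca_model a [calcium_response_model()].
#' @param n_wells replicate wells.
#' @inheritParams simulate_dose_response
#' @return data.frame of per-well summaries (`conc` = calcium in mM),
#'   ready for [build_concentration_response()].
#' @export
simulate_calcium_series <- function(ca_levels_mm,
                                    ca_model = calcium_response_model(),
                                    n_wells = 4,
                                    params = twitch_params(),
                                    schedule = beat_schedule(),
                                    duration_s = 60, dt = 0.01,
                                    noise_sd_un = 0.5, seed = 1L) {
  stopifnot(all(ca_levels_mm > 0))
  seeds <- with_seed(seed, {
    matrix(sample.int(2^30, n_wells * length(ca_levels_mm)), nrow = n_wells)
  })
  rows <- list()
  for (w in seq_len(n_wells)) {
    for (ci in seq_along(ca_levels_mm)) {
      ca <- ca_levels_mm[ci]
      p <- twitch_params(params$peak_force * calcium_scale(ca, ca_model),
                         params$time_to_peak, params$relaxation_time,
                         params$diastolic_force)
      rec <- generate_trace(schedule, p, duration_s, dt, noise_sd_un,
                            seed = seeds[w, ci],
                            well_id = sprintf("well%02d", w))
      rows[[length(rows) + 1L]] <- summarize_well(
        rec$trace, sprintf("well%02d", w), as.character(ca), ca)
    }
  }
  do.call(rbind, rows)
}
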