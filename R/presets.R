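preset_registry <- function() {
  jsonlite::fromJSON(system.file("extdata", "presets.json",
                                 package = "ehtforce"),
                     simplifyVector = TRUE)
}

#' Named simulation presets
#'
#' The preset registry (shipped as JSON under `extdata/`) pins the stated
#' experimental world: the `"spontaneous_heht"` preset encodes regular
#' spontaneous beating at 0.5 Hz with 61 uN twitches recorded for 60 s,
#' `eht_geometry_preset()` the illustrative post geometry
#' (E = 1 MPa, R = 0.5 mm, L = 10 mm) and the 0.72 mm mean tissue
#' diameter, and `eht_compound_preset()` phenomenological drug models
#' (an E-4031-like hERG blocker and a no-effect negative control in the
#' spirit of ampicillin).
#'
#' @param name preset / compound name.
#' @return `eht_preset`: list with `params` ([twitch_params()]),
#'   `schedule` ([beat_schedule()]) and `recording`
#'   (duration_s, dt, noise_sd_un).
#' @export
eht_preset <- function(name = "spontaneous_heht") {
  reg <- preset_registry()$presets
  if (!name %in% names(reg)) {
    stop_param("unknown preset '", name, "'; available: ",
               paste(names(reg), collapse = ", "))
  }
  p <- reg[[name]]
  list(params = do.call(twitch_params, as.list(p$twitch)),
       schedule = do.call(beat_schedule, as.list(p$schedule)),
       recording = as.list(p$recording))
}

#' @rdname eht_preset
#' @return `eht_geometry_preset`: list with `post` ([post_geometry()]) and
#'   `tissue` ([tissue_geometry()]).
#' @export
eht_geometry_preset <- function() {
  g <- preset_registry()$geometry
  list(post = post_geometry(g$elastic_modulus_pa, g$post_radius_mm,
                            g$post_length_mm),
       tissue = tissue_geometry(g$tissue_diameter_mm))
}

#' @rdname eht_preset
#' @return `eht_compound_preset`: list with `model`
#'   ([drug_effect_model()]), `ladder` and `conc_unit`.
#' @export
eht_compound_preset <- function(name = "e4031_like") {
  reg <- preset_registry()$compounds
  if (!name %in% names(reg)) {
    stop_param("unknown compound preset '", name, "'; available: ",
               paste(names(reg), collapse = ", "))
  }
  cp <- reg[[name]]
  list(model = drug_effect_model(name, cp$ic50_relax, cp$hill_relax,
                                 cp$ic50_force, cp$scatter_onset,
                                 cp$max_reduction),
       ladder = cp$ladder, conc_unit = cp$conc_unit)
}
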