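#' Calcium concentration-response model
#'
#' Hill model for the dependence of twitch force on extracellular calcium.
#' Force in human EHT falls by 90% when calcium is lowered from the 1.8 mM
#' baseline to 0.2 mM, and rises to a plateau between 2.2 and 3.0 mM. The
#' Hill coefficient and EC50 are solved numerically from exactly these two
#' constraints: `scale(0.2)/scale(1.8) = 0.10` and
#' `scale(2.2)/scale(3.0) = plateau_ratio` (default 0.97 -- a genuine
#' plateau; see the methods vignette).
#'
#' @param baseline_ca_mm baseline calcium, mM (fixed 1.8 in the assay
#'   medium).
#' @param low_ratio force ratio between 0.2 mM and baseline (0.10 = the 90%
#'   drop).
#' @param plateau_ratio force ratio between 2.2 and 3.0 mM.
#' @return object of class `calcium_response_model` with solved `ec50_mm`
#'   and `hill_n`.
#' @export
calcium_response_model <- function(baseline_ca_mm = 1.8, low_ratio = 0.10,
                                   plateau_ratio = 0.97) {
  stopifnot(is_scalar_num(low_ratio), low_ratio > 0, low_ratio < 1,
            is_scalar_num(plateau_ratio), plateau_ratio > 0.72,
            plateau_ratio < 1)
  # For a Hill curve h(c) = c^n / (c^n + K^n), the low-calcium constraint
  # fixes K^n given n:  x = K^n = (1-r) a b / (r b - a), a = 0.2^n,
  # b = 1.8^n, r = low_ratio.  Solve n so the plateau ratio matches.
  xn <- function(n) {
    a <- 0.2^n; b <- baseline_ca_mm^n
    (1 - low_ratio) * a * b / (low_ratio * b - a)
  }
  plateau <- function(n) {
    x <- xn(n)
    (2.2^n * (3.0^n + x)) / (3.0^n * (2.2^n + x))
  }
  # feasible only when r*b > a, i.e. n > log(1/r)/log(1.8/0.2)
  n_min <- log(1 / low_ratio) / log(baseline_ca_mm / 0.2) + 1e-6
  n <- stats::uniroot(function(n) plateau(n) - plateau_ratio,
                      lower = n_min + 0.05, upper = 40, tol = 1e-12)$root
  structure(
    list(ec50_mm = xn(n)^(1 / n), hill_n = n,
         baseline_ca = baseline_ca_mm),
    class = "calcium_response_model"
  )
}

#' Calcium amplitude multiplier
#'
#' Multiplier applied to the preset twitch amplitude at calcium
#' concentration `ca_mm`, normalised so `calcium_scale(baseline) = 1`
#' (the preset amplitude is defined at the 1.8 mM baseline medium).
#' Monotone non-decreasing in calcium; exceeds 1 above baseline, reaching
#' the plateau value by 2.2-3.0 mM.
#'
#' @param ca_mm calcium concentration, mM (vectorised, > 0).
#' @param model a [calcium_response_model()].
#' @return amplitude multiplier(s).
#' @export
calcium_scale <- function(ca_mm, model = calcium_response_model()) {
  stopifnot(inherits(model, "calcium_response_model"))
  if (any(!is.finite(ca_mm)) || any(ca_mm <= 0)) {
    stop_param("ca_mm must be > 0")
  }
  hill <- function(c) c^model$hill_n / (c^model$hill_n + model$ec50_mm^model$hill_n)
  hill(ca_mm) / hill(model$baseline_ca)
}

#' Proarrhythmic drug effect model
#'
#' Phenomenological concentration-effect map for a hERG-blocking compound:
#' a Hill-shaped slowing of relaxation (the primary readout), a separate
#' Hill-shaped force decline at higher concentrations (surrogate of
#' depolarisation block), and beat-interval scatter above a threshold
#' concentration. Maximal reductions of 30-50% were observed; the default
#' `max_reduction` is 0.4.
#'
#' @param compound compound name.
#' @param ic50_relax concentration of half-maximal relaxation slowing (same
#'   units as dosing).
#' @param hill_relax Hill coefficient (shared by the force branch).
#' @param ic50_force concentration of half-maximal force decline; defaults
#'   to `10 * ic50_relax` (force declines only at higher concentrations).
#' @param scatter_onset concentration above which beat intervals become
#'   irregular; defaults to `ic50_relax`.
#' @param max_reduction maximal fractional reduction in \[0, 1\].
#' @return object of class `drug_effect_model`.
#' @export
drug_effect_model <- function(compound, ic50_relax, hill_relax = 1,
                              ic50_force = 10 * ic50_relax,
                              scatter_onset = ic50_relax,
                              max_reduction = 0.4) {
  stopifnot(is_scalar_num(ic50_relax), ic50_relax > 0,
            is_scalar_num(hill_relax), hill_relax > 0,
            is_scalar_num(ic50_force), ic50_force > 0,
            is_scalar_num(scatter_onset), scatter_onset > 0,
            is_scalar_num(max_reduction), max_reduction >= 0,
            max_reduction <= 1)
  structure(
    list(compound = compound, ic50_relax = ic50_relax,
         hill_relax = hill_relax, ic50_force = ic50_force,
         scatter_onset = scatter_onset, max_reduction = max_reduction),
    class = "drug_effect_model"
  )
}

hill_occupancy <- function(conc, ic50, h) {
  r <- (conc / ic50)^h
  out <- ifelse(conc <= 0, 0, r / (r + 1))
  out[is.infinite(r)] <- 1  # saturated dose, not Inf/Inf
  out
}

#' @rdname drug_effect_model
#' @param model a `drug_effect_model`.
#' @param conc concentration >= 0 (vectorised).
#' @return `relax_scale`/`force_scale` return the multiplicative scale
#'   factor in `(1 - max_reduction, 1]` applied to relaxation velocity and
#'   peak force respectively.
#' @export
relax_scale <- function(model, conc) {
  1 - model$max_reduction * hill_occupancy(conc, model$ic50_relax, model$hill_relax)
}

#' @rdname drug_effect_model
#' @export
force_scale <- function(model, conc) {
  1 - model$max_reduction * hill_occupancy(conc, model$ic50_force, model$hill_relax)
}

#' Apply a drug concentration to twitch and rhythm parameters
#'
#' Returns modified copies of `params` and `schedule` describing the tissue
#' equilibrated at concentration `conc`: relaxation time divided by the
#' relaxation scale factor (slower relaxation, hence proportionally lower
#' peak relaxation velocity), peak force multiplied by the force scale
#' factor, and, above `scatter_onset`, beat-interval cv inflated by
#' `0.3 * (conc - onset)/(conc + onset)` with the schedule switched to
#' `"scattered"` mode. `conc = 0` returns the inputs unchanged.
#'
#' @inheritParams relax_scale
#' @param params a [twitch_params()].
#' @param schedule a [beat_schedule()].
#' @return list with elements `params` and `schedule`.
#' @export
apply_drug_effect <- function(params, schedule, model, conc) {
  stopifnot(inherits(params, "twitch_params"),
            inherits(schedule, "beat_schedule"),
            inherits(model, "drug_effect_model"))
  if (!is_scalar_num(conc) || conc < 0) {
    stop_param("conc must be >= 0")
  }
  if (conc == 0) return(list(params = params, schedule = schedule))
  new_params <- twitch_params(
    peak_force_un = params$peak_force * force_scale(model, conc),
    time_to_peak_s = params$time_to_peak,
    relaxation_time_s = params$relaxation_time / relax_scale(model, conc),
    diastolic_force_un = params$diastolic_force
  )
  cv <- schedule$interval_cv
  mode <- schedule$irregularity_mode
  if (conc > model$scatter_onset) {
    cv <- cv + 0.3 * (conc - model$scatter_onset) / (conc + model$scatter_onset)
    mode <- "scattered"
  }
  new_schedule <- beat_schedule(schedule$base_frequency, cv, mode)
  list(params = new_params, schedule = new_schedule)
}

#' Chronotropy model (isoprenaline / carbachol)
#'
#' The beta-adrenergic agonist isoprenaline raises spontaneous beating
#' frequency; the muscarinic agonist carbachol reverses the effect back to
#' baseline. Effect sizes are phenomenological (the response is modest
#' compared to adult myocardium); default gain 1.3.
#'
#' @param isoprenaline_freq_gain multiplicative frequency gain, > 1.
#' @param carbachol_reversal logical; carbachol restores baseline frequency.
#' @return object of class `chronotropy_model`.
#' @export
chronotropy_model <- function(isoprenaline_freq_gain = 1.3,
                              carbachol_reversal = TRUE) {
  stopifnot(is_scalar_num(isoprenaline_freq_gain),
            isoprenaline_freq_gain > 1, is.logical(carbachol_reversal))
  structure(
    list(isoprenaline_freq_gain = isoprenaline_freq_gain,
         carbachol_reversal = carbachol_reversal),
    class = "chronotropy_model"
  )
}

#' @rdname chronotropy_model
#' @param schedule a [beat_schedule()].
#' @param model a `chronotropy_model`.
#' @param isoprenaline,carbachol logical condition flags.
#' @return `apply_chronotropy` returns a modified [beat_schedule()].
#' @export
apply_chronotropy <- function(schedule, model, isoprenaline = FALSE,
                              carbachol = FALSE) {
  stopifnot(inherits(schedule, "beat_schedule"),
            inherits(model, "chronotropy_model"))
  gain <- 1
  if (isoprenaline) {
    gain <- model$isoprenaline_freq_gain
    if (carbachol && model$carbachol_reversal) gain <- 1
  }
  beat_schedule(schedule$base_frequency * gain, schedule$interval_cv,
                schedule$irregularity_mode)
}
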