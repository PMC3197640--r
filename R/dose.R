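#' Cumulative dose-response experiment container
#'
#' Holds per-(well, condition) recording summaries for one compound tested
#' at cumulative concentrations against a per-well baseline. `data` must
#' have one `"baseline"` row per well plus one row per tested
#' concentration, with numeric summary columns (at least `mean_force_un`,
#' `frequency_hz`, `mean_contraction_velocity`, `mean_relaxation_velocity`,
#' `idr`).
#'
#' @param compound compound name.
#' @param ladder strictly increasing concentration ladder (units are the
#'   caller's; stored in `conc_unit`).
#' @param data data.frame with columns `well_id`, `condition` ("baseline"
#'   or the concentration as character), `conc` (numeric, `NA` for
#'   baseline) and summary columns.
#' @param conc_unit concentration unit label (e.g. "nM").
#' @param equilibration_min equilibration time before measurement
#'   (metadata; 30 min in the standard protocol).
#' @return object of class `dose_response_experiment`.
#' @export
dose_response_experiment <- function(compound, ladder, data,
                                     conc_unit = "nM",
                                     equilibration_min = 30) {
  stopifnot(is.character(compound), is.numeric(ladder), is.data.frame(data))
  if (length(ladder) && any(diff(ladder) <= 0)) {
    stop_param("concentration ladder must be strictly increasing")
  }
  need <- c("well_id", "condition", "conc")
  if (!all(need %in% names(data))) {
    stop_param("experiment data needs columns ", paste(need, collapse = ", "))
  }
  wells <- unique(data$well_id)
  has_base <- vapply(wells, function(w) {
    any(data$well_id == w & data$condition == "baseline")
  }, logical(1))
  if (!all(has_base)) {
    stop_param("every well needs a baseline recording: missing for ",
               paste(wells[!has_base], collapse = ", "))
  }
  structure(
    list(compound = compound, ladder = ladder, data = data,
         conc_unit = conc_unit, equilibration_min = equilibration_min),
    class = "dose_response_experiment"
  )
}

#' Normalise summaries to per-well baseline (percent of baseline)
#'
#' Each parameter of each well/condition is divided by that well's
#' baseline value and multiplied by 100, so every baseline row reads
#' exactly 100. A zero baseline value yields `NA` for that well/parameter
#' (flagged, not fabricated). Normalising an already-normalised table is
#' the identity.
#'
#' @param x a [dose_response_experiment()] or a data.frame with `well_id`,
#'   `condition` ("baseline" marks the reference row) and numeric
#'   parameter columns.
#' @param parameters parameter columns to normalise; defaults to all
#'   numeric columns except `conc`.
#' @return data.frame like the input with parameters in percent of
#'   baseline.
#' @export
normalize_to_baseline <- function(x, parameters = NULL) {
  df <- if (inherits(x, "dose_response_experiment")) x$data else x
  stopifnot(is.data.frame(df), all(c("well_id", "condition") %in% names(df)))
  if (is.null(parameters)) {
    num <- vapply(df, is.numeric, logical(1))
    parameters <- setdiff(names(df)[num], c("conc"))
  }
  out <- df
  for (w in unique(df$well_id)) {
    base_row <- which(df$well_id == w & df$condition == "baseline")
    if (length(base_row) != 1L) {
      stop_param("well ", w, " must have exactly one baseline row")
    }
    rows <- which(df$well_id == w)
    for (p in parameters) {
      b <- df[[p]][base_row]
      out[[p]][rows] <- if (is.na(b) || b == 0) NA_real_ else
        df[[p]][rows] / b * 100
    }
  }
  out
}

#' Paired Student's t-test
#'
#' Classical paired two-tailed t-test on the within-well differences
#' (treated minus baseline), p from the t distribution with n-1 degrees of
#' freedom. Degenerate cases: all differences zero gives p = 1; zero
#' variance with non-zero mean gives p = 0 with `degenerate = TRUE`.
#'
#' @param baseline,treated numeric vectors of equal length >= 2, paired by
#'   well.
#' @return list of class `paired_t`: `t`, `p_value`, `df`,
#'   `mean_difference`, `degenerate`.
#' @export
paired_t_test <- function(baseline, treated) {
  n <- length(baseline)
  if (n < 2 || length(treated) != n) {
    stop_param("paired_t_test needs two equal-length vectors (n >= 2)")
  }
  d <- treated - baseline
  sd_d <- stats::sd(d)
  if (sd_d == 0) {
    p <- if (mean(d) == 0) 1 else 0
    return(structure(list(t = if (mean(d) == 0) 0 else Inf * sign(mean(d)),
                          p_value = p, df = n - 1,
                          mean_difference = mean(d),
                          degenerate = mean(d) != 0),
                     class = "paired_t"))
  }
  t <- mean(d) / (sd_d / sqrt(n))
  structure(list(t = t, p_value = 2 * stats::pt(-abs(t), df = n - 1),
                 df = n - 1, mean_difference = mean(d), degenerate = FALSE),
            class = "paired_t")
}

default_direction <- function(parameter) {
  if (parameter == "idr") "increase" else "decrease"
}

#' Threshold concentration for a contractility parameter
#'
#' Reproduces the threshold-table logic: for each ladder concentration the
#' per-well treated values are compared against the per-well baseline
#' values -- with a paired Student's t-test for contractility parameters
#' (relaxation velocity, force, ...) or an exact Mann-Whitney U test on
#' per-well IDR values for beat-interval scatter. The threshold is the
#' lowest concentration with two-sided p < `alpha` *and* the effect in the
#' expected direction (decrease for velocities/force, increase for IDR);
#' `NA` if no concentration qualifies. No multiple-testing correction is
#' applied across the ladder (flagged in the result).
#'
#' @param experiment a [dose_response_experiment()].
#' @param parameter summary column to test (e.g.
#'   `"mean_relaxation_velocity"`, `"idr"`).
#' @param procedure `"t"` (paired t) or `"mannwhitney"` (exact U on per-well
#'   values).
#' @param alpha significance level (0.05 in the screening protocol).
#' @param direction `"decrease"` or `"increase"`; default chosen from the
#'   parameter.
#' @return list of class `threshold_result`: `compound`, `parameter`,
#'   `procedure`, `threshold` (concentration or `NA`), `table`
#'   (per-concentration p-values and directions),
#'   `multiplicity_corrected = FALSE`.
#' @export
threshold_concentration <- function(experiment, parameter,
                                    procedure = c("t", "mannwhitney"),
                                    alpha = 0.05,
                                    direction = default_direction(parameter)) {
  stopifnot(inherits(experiment, "dose_response_experiment"))
  procedure <- match.arg(procedure)
  direction <- match.arg(direction, c("decrease", "increase"))
  df <- experiment$data
  if (!parameter %in% names(df)) stop_param("unknown parameter: ", parameter)
  wells <- sort(unique(df$well_id))
  if (length(wells) < 2) stop_param("need >= 2 replicate wells")
  get_vals <- function(cond) {
    vapply(wells, function(w) {
      v <- df[[parameter]][df$well_id == w & df$condition == cond]
      if (length(v) != 1L) NA_real_ else v
    }, numeric(1))
  }
  base <- get_vals("baseline")
  rows <- lapply(experiment$ladder, function(conc) {
    treat <- get_vals(as.character(conc))
    ok <- is.finite(base) & is.finite(treat)
    if (sum(ok) < 2) {
      return(data.frame(conc = conc, p_value = NA_real_,
                        effect = NA_real_, direction_ok = NA))
    }
    if (procedure == "t") {
      res <- paired_t_test(base[ok], treat[ok])
      eff <- res$mean_difference
    } else {
      res <- mann_whitney_u(base[ok], treat[ok], mode = "exact")
      eff <- stats::median(treat[ok]) - stats::median(base[ok])
    }
    dir_ok <- if (direction == "decrease") eff < 0 else eff > 0
    data.frame(conc = conc, p_value = res$p_value, effect = eff,
               direction_ok = dir_ok)
  })
  tab <- do.call(rbind, rows)
  hit <- which(!is.na(tab$p_value) & tab$p_value < alpha & tab$direction_ok)
  structure(
    list(compound = experiment$compound, parameter = parameter,
         procedure = procedure, alpha = alpha, direction = direction,
         threshold = if (length(hit)) tab$conc[min(hit)] else NA_real_,
         table = tab, multiplicity_corrected = FALSE),
    class = "threshold_result"
  )
}

#' Threshold-table row for one compound
#'
#' Combines the two screening procedures into one row: threshold for a
#' significant decrease in relaxation velocity (paired t) and threshold for
#' significantly increased RR-scatter (exact Mann-Whitney on per-well IDR).
#'
#' @inheritParams threshold_concentration
#' @return data.frame with one row: `compound`, `threshold_relaxation`,
#'   `threshold_scatter`; attribute `details` holds both
#'   `threshold_result` objects.
#' @export
threshold_table <- function(experiment, alpha = 0.05) {
  relax <- threshold_concentration(experiment, "mean_relaxation_velocity",
                                   procedure = "t", alpha = alpha)
  scatter <- threshold_concentration(experiment, "idr",
                                     procedure = "mannwhitney", alpha = alpha)
  out <- data.frame(compound = experiment$compound,
                    threshold_relaxation = relax$threshold,
                    threshold_scatter = scatter$threshold)
  attr(out, "details") <- list(relaxation = relax, scatter = scatter)
  out
}

#' Concentration-response table (calcium)
#'
#' Aggregates per-well recording summaries into an ordered
#' concentration-response table of mean +/- sd force and frequency.
#'
#' @param summaries data.frame with columns `conc`, `well_id`,
#'   `mean_force_un`, `frequency_hz` (one row per well and level).
#' @return data.frame ordered by `conc`: `conc`, `n_wells`, `force_mean`,
#'   `force_sd`, `freq_mean`, `freq_sd`.
#' @export
build_concentration_response <- function(summaries) {
  stopifnot(is.data.frame(summaries),
            all(c("conc", "well_id", "mean_force_un", "frequency_hz") %in%
                  names(summaries)))
  levels <- sort(unique(summaries$conc))
  rows <- lapply(levels, function(cc) {
    s <- summaries[summaries$conc == cc, ]
    data.frame(conc = cc, n_wells = nrow(s),
               force_mean = mean(s$mean_force_un),
               force_sd = stats::sd(s$mean_force_un),
               freq_mean = mean(s$frequency_hz),
               freq_sd = stats::sd(s$frequency_hz))
  })
  do.call(rbind, rows)
}
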