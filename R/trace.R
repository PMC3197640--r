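#' Contraction trace
#'
#' A uniformly sampled time series of post deflection or force for one EHT
#' recording. Stored as a data.frame with columns `time_s`, `value` and
#' attributes `unit` ("uN" for force, "um" for deflection), `sample_rate`
#' (Hz) and `well_id`.
#'
#' @param time_s strictly increasing uniform time grid, s.
#' @param value finite numeric values, same length as `time_s`.
#' @param unit `"uN"` or `"um"`.
#' @param well_id label of the source well.
#' @return object of classes `contraction_trace`, `data.frame`.
#' @export
contraction_trace <- function(time_s, value, unit = c("uN", "um"),
                              well_id = "well") {
  unit <- match.arg(unit)
  stopifnot(is.numeric(time_s), is.numeric(value),
            length(time_s) == length(value), length(time_s) >= 2)
  if (any(!is.finite(value))) stop_param("trace values must be finite")
  dt <- diff(time_s)
  if (any(dt <= 0)) stop_param("time grid must be strictly increasing")
  if (diff(range(dt)) > 1e-6 * mean(dt)) {
    stop_param("time grid must be uniform; use read_trace() to resample ",
               "jittered input")
  }
  structure(
    data.frame(time_s = time_s, value = value),
    unit = unit,
    sample_rate = 1 / mean(dt),
    well_id = well_id,
    class = c("contraction_trace", "data.frame")
  )
}

trace_unit <- function(trace) attr(trace, "unit")
trace_rate <- function(trace) attr(trace, "sample_rate")

#' @export
print.contraction_trace <- function(x, ...) {
  cat(sprintf(
    "Contraction trace '%s': %d samples at %.4g Hz, %.4g s, unit %s\n",
    attr(x, "well_id"), nrow(x), attr(x, "sample_rate"),
    x$time_s[nrow(x)] - x$time_s[1], attr(x, "unit")))
  invisible(x)
}

#' Convert a deflection trace to force through post mechanics
#'
#' @param trace a [contraction_trace()] in `"um"` (deflection).
#' @param geom a [post_geometry()].
#' @return a force trace (`"uN"`), same grid and well.
#' @export
trace_to_force <- function(trace, geom) {
  stopifnot(inherits(trace, "contraction_trace"))
  if (trace_unit(trace) == "uN") return(trace)
  contraction_trace(trace$time_s, force_from_deflection_um(trace$value, geom),
                    unit = "uN", well_id = attr(trace, "well_id"))
}

#' @rdname trace_to_force
#' @return `trace_to_deflection` returns a deflection trace (`"um"`).
#' @export
trace_to_deflection <- function(trace, geom) {
  stopifnot(inherits(trace, "contraction_trace"))
  if (trace_unit(trace) == "um") return(trace)
  contraction_trace(trace$time_s, deflection_from_force_un(trace$value, geom),
                    unit = "um", well_id = attr(trace, "well_id"))
}

#' Read / write contraction traces as CSV
#'
#' Traces are stored as plain CSV with header `time_s,value,value_unit`
#' (the unit column holds the same tag on every row). On reading, the time
#' grid is validated: jitter up to 1% of the median sample interval is
#' tolerated silently; larger jitter (up to 20%) causes linear resampling
#' onto a uniform grid and sets the attribute `resampled = TRUE`;
#' non-monotone time or a missing/unknown unit is a format error.
#'
#' @param path file path.
#' @param unit optional unit override (`"uN"` or `"um"`); defaults to the
#'   `value_unit` column, which must then be present.
#' @param well_id well label; defaults to the file name.
#' @return a [contraction_trace()].
#' @export
read_trace <- function(path, unit = NULL, well_id = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_s", "value") %in% names(df))) {
    stop_param("trace CSV needs columns time_s,value[,value_unit]: ", path)
  }
  if (is.null(unit)) {
    if (!"value_unit" %in% names(df)) {
      stop_param("no unit declared: pass `unit` or add a value_unit column")
    }
    unit <- unique(df$value_unit)
    if (length(unit) != 1L) stop_param("inconsistent value_unit column")
  }
  if (!unit %in% c("uN", "um")) stop_param("unknown unit: ", unit)
  t <- df$time_s
  if (any(diff(t) <= 0)) stop_param("non-monotone time column in ", path)
  if (is.null(well_id)) well_id <- sub("\\.csv$", "", basename(path))
  dt <- stats::median(diff(t))
  jitter <- max(abs(diff(t) - dt))
  if (jitter > 0.01 * dt) {
    if (jitter > 0.2 * dt) {
      stop_param("time grid jitter exceeds 20% of the sample interval")
    }
    grid <- seq(t[1], t[length(t)], by = dt)
    v <- stats::approx(t, df$value, xout = grid)$y
    tr <- contraction_trace(grid, v, unit = unit, well_id = well_id)
    attr(tr, "resampled") <- TRUE
    return(tr)
  }
  # snap sub-tolerance jitter onto the exact uniform grid
  grid <- seq(t[1], by = dt, length.out = length(t))
  contraction_trace(grid, df$value, unit = unit, well_id = well_id)
}

#' @rdname read_trace
#' @param trace a [contraction_trace()].
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "contraction_trace"))
  df <- data.frame(time_s = sprintf("%.17g", trace$time_s),
                   value = sprintf("%.17g", trace$value),
                   value_unit = trace_unit(trace))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read ground truth sidecar
#'
#' Ground truth for a synthetic trace is stored as a JSON sidecar so a
#' generated fixture can be re-analysed later and compared against the
#' events that were actually rendered.
#'
#' @param truth a `ground_truth` object from [generate_trace()].
#' @param path JSON file path.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  jsonlite::write_json(
    list(event_times = truth$event_times,
         peak_force_un = truth$peak_force_un,
         onset_times = truth$onset_times,
         overlap = truth$overlap),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
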