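#' Experiment manifest
#'
#' Binds one compound experiment together: the recordings per well and
#' condition, the post geometry used to convert deflection traces, the
#' concentration ladder and the significance level. Serialisable to JSON
#' with [write_manifest()] / [read_manifest()]; recording paths are
#' resolved relative to the manifest file.
#'
#' @param recordings data.frame with columns `well_id`, `condition`
#'   ("baseline" or the concentration as character), `path`, `unit`
#'   ("uN" or "um").
#' @param compound compound name.
#' @param ladder numeric concentration ladder (may be empty for plain
#'   contractility runs).
#' @param conc_unit concentration unit label.
#' @param geometry optional list
#'   `(elastic_modulus_pa, post_radius_mm, post_length_mm)`; required if
#'   any recording is in deflection units.
#' @param alpha significance level for threshold calls.
#' @return object of class `experiment_manifest`.
#' @export
experiment_manifest <- function(recordings, compound = "unknown",
                                ladder = numeric(), conc_unit = "nM",
                                geometry = NULL, alpha = 0.05) {
  stopifnot(is.data.frame(recordings))
  if (nrow(recordings) &&
      !all(c("well_id", "condition", "path", "unit") %in% names(recordings))) {
    stop_param("recordings needs columns well_id, condition, path, unit")
  }
  structure(list(compound = compound, ladder = ladder,
                 conc_unit = conc_unit, geometry = geometry,
                 alpha = alpha, recordings = recordings),
            class = "experiment_manifest")
}

#' @rdname experiment_manifest
#' @param path JSON file path.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "experiment_manifest"))
  jsonlite::write_json(unclass(manifest), path, digits = NA,
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname experiment_manifest
#' @export
read_manifest <- function(path) {
  m <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  rec <- as.data.frame(m$recordings)
  if (nrow(rec)) {
    abs <- file.path(dirname(path), rec$path)
    rec$path <- ifelse(file.exists(rec$path), rec$path, abs)
  }
  experiment_manifest(rec, compound = m$compound,
                      ladder = as.numeric(m$ladder),
                      conc_unit = m$conc_unit,
                      geometry = m$geometry, alpha = m$alpha)
}

manifest_hash <- function(manifest) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(manifest), tmp, digits = NA,
                       auto_unbox = TRUE, null = "null")
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline over a manifest
#'
#' For every recording: read the trace, convert deflection to force
#' through the post geometry where needed, detect and measure twitches,
#' summarise, and compute the per-recording interval IDR. If a
#' concentration ladder is present, per-well baseline normalisation and
#' the two threshold procedures are run on top. Failures are isolated per
#' recording (recorded in `errors`, the run continues). The report embeds
#' the package version and a config hash of the manifest, so identical
#' manifests reproduce identical report bodies.
#'
#' @param manifest an [experiment_manifest()].
#' @param cfg a [detection_settings()].
#' @return list of class `analysis_report`: `version`, `config_hash`,
#'   `compound`, `wells` (per-recording summary table), `errors`,
#'   `normalized` (percent-of-baseline table or `NULL`), `thresholds`
#'   (one-row threshold table or `NULL`), `timestamp`.
#' @export
run_pipeline <- function(manifest, cfg = detection_settings()) {
  stopifnot(inherits(manifest, "experiment_manifest"))
  geom <- if (!is.null(manifest$geometry)) {
    post_geometry(manifest$geometry$elastic_modulus_pa,
                  manifest$geometry$post_radius_mm,
                  manifest$geometry$post_length_mm)
  } else NULL
  rec <- manifest$recordings
  report <- list(version = as.character(utils::packageVersion("ehtforce")),
                 config_hash = manifest_hash(manifest),
                 compound = manifest$compound,
                 wells = NULL, errors = list(), normalized = NULL,
                 thresholds = NULL,
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  class(report) <- "analysis_report"
  if (is.null(rec) || nrow(rec) == 0) {
    warning("empty manifest: nothing to analyze")
    return(report)
  }
  rows <- list()
  for (i in seq_len(nrow(rec))) {
    r <- rec[i, ]
    res <- tryCatch({
      tr <- read_trace(r$path, unit = r$unit, well_id = r$well_id)
      conc <- suppressWarnings(as.numeric(r$condition))
      summarize_well(tr, r$well_id, r$condition, conc, geom = geom,
                     cfg = cfg)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      report$errors[[length(report$errors) + 1L]] <-
        list(well_id = r$well_id, condition = r$condition,
             message = conditionMessage(res))
    } else {
      rows[[length(rows) + 1L]] <- res
    }
  }
  if (length(rows)) report$wells <- do.call(rbind, rows)
  if (length(manifest$ladder) && !is.null(report$wells) &&
      !length(report$errors)) {
    expt <- dose_response_experiment(manifest$compound, manifest$ladder,
                                     report$wells,
                                     conc_unit = manifest$conc_unit)
    report$normalized <- normalize_to_baseline(expt)
    tt <- threshold_table(expt, alpha = manifest$alpha)
    attr(tt, "details") <- NULL
    report$thresholds <- tt
  }
  report
}

#' Write an analysis report to JSON
#'
#' The serialised body is deterministic for identical inputs apart from
#' the `timestamp` field.
#'
#' @param report an `analysis_report` from [run_pipeline()].
#' @param path JSON file path.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "analysis_report"))
  jsonlite::write_json(unclass(report), path, digits = NA,
                       auto_unbox = TRUE, pretty = TRUE, null = "null",
                       dataframe = "rows")
  invisible(path)
}
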