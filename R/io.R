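# Plain-text interchange: recordings as CSV with a `# fs=` header line,
# ground truth / configs / reports as JSON.

#' Write and read paired recordings as CSV
#'
#' The CSV carries a `# fs=<value>` comment header followed by columns
#' `time_s,icp_mmHg,b4c_um,abp_mmHg`. The session config, when present in
#' the recording metadata, is written to a JSON sidecar `<path>.config.json`
#' so a re-read recording keeps its epoch information.
#'
#' @param recording a `paired_recording`.
#' @param path output CSV path.
#' @return `write_recording()` returns `path` invisibly; `read_recording()`
#'   returns a `paired_recording`.
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "paired_recording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%.10g", recording$fs), con)
  utils::write.table(
    data.frame(time_s = recording$time_s,
               icp_mmHg = recording$icp_mmHg,
               b4c_um = recording$b4c_um,
               abp_mmHg = recording$abp_mmHg),
    con, sep = ",", row.names = FALSE, quote = FALSE)
  if (inherits(recording$metadata, "session_config")) {
    write_session_config(recording$metadata,
                         paste0(path, ".config.json"))
  }
  invisible(path)
}

#' @rdname write_recording
#' @param config_path optional explicit config sidecar path; defaults to
#'   `<path>.config.json` when that file exists.
#' @export
read_recording <- function(path, config_path = NULL) {
  first <- readLines(path, n = 1)
  fs <- as.numeric(sub("^#\\s*fs=", "", first))
  if (!is.finite(fs)) stop("missing `# fs=` header", call. = FALSE)
  d <- utils::read.csv(path, comment.char = "#")
  if (is.null(config_path)) {
    cand <- paste0(path, ".config.json")
    if (file.exists(cand)) config_path <- cand
  }
  metadata <- if (!is.null(config_path)) read_session_config(config_path)
  else list()
  structure(list(time_s = d$time_s, icp_mmHg = d$icp_mmHg,
                 b4c_um = d$b4c_um, abp_mmHg = d$abp_mmHg,
                 fs = fs, metadata = metadata),
            class = "paired_recording")
}

#' Write and read session configs as JSON
#'
#' @param config a [session_config()].
#' @param path JSON path.
#' @export
write_session_config <- function(config, path) {
  stopifnot(inherits(config, "session_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_session_config
#' @export
read_session_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(session_config, x)
}

#' Write and read ground truth as JSON
#'
#' @param truth a `ground_truth`.
#' @param path JSON path.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  jsonlite::write_json(unclass(truth), path, digits = NA)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$artifact_beat_indices <- as.integer(x$artifact_beat_indices)
  structure(x, class = "ground_truth")
}

#' Write and read session reports as JSON
#'
#' Reports round-trip: the parsed file reproduces the report's tabular
#' content exactly. A `schema_version` field marks the layout.
#'
#' @param report an `icpw_session`.
#' @param path JSON path.
#' @export
write_session_report <- function(report, path) {
  stopifnot(inherits(report, "icpw_session"))
  payload <- list(schema_version = "1.0",
                  per_minute = report$per_minute,
                  minute_icp = report$minute_icp,
                  summary = report$summary,
                  mean_icp_baseline = report$mean_icp_baseline,
                  mean_icp_compression = report$mean_icp_compression,
                  flags = report$flags,
                  n_beats = report$n_beats,
                  group = report$group)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_session_report
#' @export
read_session_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$per_minute <- as.data.frame(x$per_minute)
  x$minute_icp <- as.data.frame(x$minute_icp)
  x$summary <- as.data.frame(x$summary)
  x
}

#' Flat per-minute CSV of a session report
#'
#' @param report an `icpw_session`.
#' @param path CSV path.
#' @export
write_session_csv <- function(report, path) {
  stopifnot(inherits(report, "icpw_session"))
  utils::write.csv(report$per_minute, path, row.names = FALSE)
  invisible(path)
}

#' Write a cohort validation report (JSON + delta-table CSV)
#'
#' @param report an `icpw_cohort_validation`.
#' @param path JSON path; the delta table is also written next to it as
#'   `<path>.delta.csv`.
#' @export
write_cohort_report <- function(report, path) {
  stopifnot(inherits(report, "icpw_cohort_validation"))
  strip <- function(b) {
    if (is.null(b)) return(NULL)
    lapply(b, function(el) if (is.list(el)) unclass(el) else el)
  }
  payload <- list(schema_version = "1.0",
                  n_sessions = report$n_sessions,
                  pooled = strip(report$pooled),
                  per_group = lapply(report$per_group, strip),
                  delta_table = report$delta_table,
                  icp_epochs = report$icp_epochs)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  utils::write.csv(report$delta_table, paste0(path, ".delta.csv"),
                   row.names = FALSE)
  invisible(path)
}
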