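#' Persist a MEG session to disk
#'
#' Writes a session as a small directory-style container under a common
#' path prefix: the sensor-by-sample data matrix and the sensor geometry as
#' Arrow Feather files (doubles round-trip bitwise), the event schedule as
#' CSV, and the generator configuration plus metadata as a JSON sidecar.
#' The generator's internal ground-truth templates are session diagnostics
#' and are not part of the interchange format.
#'
#' @param session A `meg_session`.
#' @param prefix Path prefix; files `<prefix>_data.feather`,
#'   `<prefix>_events.csv`, `<prefix>_sensors.feather`,
#'   `<prefix>_meta.json` are created.
#' @return `prefix`, invisibly.
#' @export
write_meg_session <- function(session, prefix) {
  stopifnot(inherits(session, "meg_session"))
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  df <- as.data.frame(t(session$data))
  names(df) <- sprintf("ch%03d", seq_len(nrow(session$data)))
  arrow::write_feather(df, paste0(prefix, "_data.feather"))
  utils::write.csv(session$schedule, paste0(prefix, "_events.csv"),
                   row.names = FALSE)
  arr <- session$array
  sens <- data.frame(
    x = arr$positions[, 1], y = arr$positions[, 2], z = arr$positions[, 3],
    ox = arr$orientations[, 1], oy = arr$orientations[, 2],
    oz = arr$orientations[, 3],
    parietal = arr$parietal_mask
  )
  arrow::write_feather(sens, paste0(prefix, "_sensors.feather"))
  meta <- list(
    schema_version = "1",
    kind = session$kind,
    rate = session$rate,
    lowpass = session$lowpass,
    seed = session$seed,
    head_radius = arr$head_radius,
    array_seed = arr$seed,
    config = jsonlite::serializeJSON(session$config)
  )
  jsonlite::write_json(meta, paste0(prefix, "_meta.json"), auto_unbox = TRUE)
  invisible(prefix)
}

#' Read a MEG session written by [write_meg_session()]
#'
#' Validates the container (all four files present, supported schema
#' version, event times non-decreasing) and reconstructs the session;
#' data arrays round-trip bitwise.
#'
#' @param prefix Path prefix used when writing.
#' @return A `meg_session` (without the generator's `truth` diagnostics).
#' @export
read_meg_session <- function(prefix) {
  paths <- paste0(prefix, c("_data.feather", "_events.csv",
                            "_sensors.feather", "_meta.json"))
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop_smf("format_error", "session container incomplete; missing: %s",
             paste(basename(missing), collapse = ", "))
  }
  meta <- tryCatch(jsonlite::read_json(paths[4]),
                   error = function(e) stop_smf("format_error",
                                                "unreadable metadata sidecar"))
  if (!identical(meta$schema_version, "1")) {
    stop_smf("format_error", "unsupported session schema version '%s'",
             meta$schema_version %||% "<missing>")
  }
  df <- tryCatch(arrow::read_feather(paths[1]),
                 error = function(e) stop_smf("format_error",
                                              "unreadable or truncated data file"))
  schedule <- utils::read.csv(paths[2], stringsAsFactors = FALSE)
  if (is.unsorted(schedule$time_s)) {
    stop_smf("validation_error", "event times must be non-decreasing")
  }
  sens <- as.data.frame(tryCatch(
    arrow::read_feather(paths[3]),
    error = function(e) stop_smf("format_error",
                                 "unreadable or truncated sensor file")))
  array <- structure(
    list(
      positions = as.matrix(sens[, c("x", "y", "z")]),
      orientations = as.matrix(sens[, c("ox", "oy", "oz")]),
      parietal_mask = as.logical(sens$parietal),
      n_sensors = nrow(sens),
      head_radius = meta$head_radius,
      seed = meta$array_seed
    ),
    class = "sensor_array"
  )
  dimnames(array$positions) <- list(NULL, c("x", "y", "z"))
  dimnames(array$orientations) <- list(NULL, c("x", "y", "z"))
  config <- jsonlite::unserializeJSON(meta$config)
  data <- t(as.matrix(df))
  dimnames(data) <- NULL
  structure(
    list(data = data, rate = meta$rate, lowpass = meta$lowpass,
         schedule = schedule, array = array, config = config,
         truth = NULL, kind = meta$kind, seed = meta$seed),
    class = "meg_session"
  )
}
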