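node_schema_paths <- c(
  "sensor/acc/x", "sensor/acc/y", "sensor/acc/z",
  "sensor/gyro/x", "sensor/gyro/y", "sensor/gyro/z",
  "sensor/temp", "sensor/ambient", "sensor/BPM", "sensor/SpO2",
  "sensor/speed", "sensor/alert", "timestamp"
)

#' Firebase-style key-path records
#'
#' Cloud-database interchange format: one sample is flattened to a mapping
#' from slash-delimited node paths to numeric values, mirroring the layout a
#' glove firmware would write to a realtime database (`sensor/acc/{x,y,z}`,
#' `sensor/gyro/{x,y,z}`, `sensor/temp`, `sensor/BPM`, `sensor/alert`,
#' `timestamp`). The schema additionally carries `sensor/SpO2`,
#' `sensor/ambient` and `sensor/speed` so that a session row round-trips
#' losslessly. `sensor/alert` is constrained to 0/1 and every schema path is
#' present exactly once.
#'
#' @param sample One-row data frame (or single row of a [vital_session]) with
#'   the session channel columns.
#' @param imu Optional one-row data frame with columns `gyro_x`, `gyro_y`,
#'   `gyro_z` (deg/s) and optionally `acc_x`, `acc_y`, `acc_z` (g). Missing
#'   IMU channels are written as 0.
#' @return `as_node_record()` returns a named list of numeric scalars keyed by
#'   node path; `from_node_record()` returns a list with elements `sample`
#'   (one-row tibble) and `imu` (one-row tibble).
#' @examples
#' s <- load_fixture("raw_resting")
#' rec <- as_node_record(s[4, ])
#' rec[["sensor/BPM"]]
#' from_node_record(rec, index = 4)$sample$hr_bpm
#' @export
as_node_record <- function(sample, imu = NULL) {
  stopifnot(is.data.frame(sample), nrow(sample) == 1L)
  g <- function(df, col) if (!is.null(df) && col %in% names(df)) as.numeric(df[[col]][1]) else 0
  rec <- list(
    "sensor/acc/x" = g(imu, "acc_x"), "sensor/acc/y" = g(imu, "acc_y"),
    "sensor/acc/z" = g(imu, "acc_z"),
    "sensor/gyro/x" = g(imu, "gyro_x"), "sensor/gyro/y" = g(imu, "gyro_y"),
    "sensor/gyro/z" = g(imu, "gyro_z"),
    "sensor/temp" = as.numeric(sample$body_c),
    "sensor/ambient" = as.numeric(sample$ambient_c),
    "sensor/BPM" = as.numeric(sample$hr_bpm),
    "sensor/SpO2" = as.numeric(sample$spo2_pct),
    "sensor/speed" = as.numeric(sample$speed_cm_s),
    "sensor/alert" = as.numeric(sample$alert),
    "timestamp" = as.numeric(sample$time_s)
  )
  validate_node_record(rec)
  rec
}

#' @rdname as_node_record
#' @param record A named list as returned by `as_node_record()`.
#' @param index Sample ordinal to attach to the reconstructed row.
#' @export
from_node_record <- function(record, index = 1L) {
  validate_node_record(record)
  sample <- tibble::tibble(
    index = as.integer(index),
    time_s = record[["timestamp"]],
    hr_bpm = record[["sensor/BPM"]],
    spo2_pct = record[["sensor/SpO2"]],
    ambient_c = record[["sensor/ambient"]],
    body_c = record[["sensor/temp"]],
    speed_cm_s = record[["sensor/speed"]],
    alert = record[["sensor/alert"]]
  )
  imu <- tibble::tibble(
    gyro_x = record[["sensor/gyro/x"]], gyro_y = record[["sensor/gyro/y"]],
    gyro_z = record[["sensor/gyro/z"]],
    acc_x = record[["sensor/acc/x"]], acc_y = record[["sensor/acc/y"]],
    acc_z = record[["sensor/acc/z"]]
  )
  list(sample = sample, imu = imu)
}

validate_node_record <- function(record) {
  if (!is.list(record)) abort("node record must be a named list")
  missing_paths <- setdiff(node_schema_paths, names(record))
  if (length(missing_paths) > 0L) {
    abort(paste0("node record missing path(s): ",
                 paste(missing_paths, collapse = ", ")))
  }
  dup <- names(record)[duplicated(names(record))]
  if (length(dup) > 0L) {
    abort(paste0("duplicated node path(s): ", paste(unique(dup), collapse = ", ")))
  }
  if (!record[["sensor/alert"]] %in% c(0, 1)) {
    abort("sensor/alert must be 0 or 1")
  }
  invisible(record)
}

#' @rdname as_node_record
#' @param path File path for JSON serialisation.
#' @export
write_node_record <- function(record, path) {
  validate_node_record(record)
  jsonlite::write_json(record, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname as_node_record
#' @export
read_node_record <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = FALSE)
  rec <- lapply(rec, as.numeric)
  validate_node_record(rec)
  rec
}
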