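#' Vital-sign monitoring sessions
#'
#' A vital session is a tibble of per-sample glove readings with one row per
#' sample and the columns `index` (1-based sample ordinal), `time_s` (seconds
#' from session start), `hr_bpm` (heart rate, beats/min), `spo2_pct` (blood
#' oxygen saturation, percent), `ambient_c` and `body_c` (temperatures, deg C),
#' `speed_cm_s` (linear speed, cm/s) and `alert` (binary flag). The activity
#' phase (`"resting"`, `"walking"` or `"running"`) and the uniform sampling
#' period in seconds travel with the object as attributes.
#'
#' `vital_session()` builds and validates a session from any data frame that
#' carries the five measurement channels and the alert column; `index` and
#' `time_s` are derived from row order and `sample_period_s` when absent.
#'
#' @param data A data frame with columns `hr_bpm`, `spo2_pct`, `ambient_c`,
#'   `body_c`, `speed_cm_s` and `alert`, optionally `index` and `time_s`.
#' @param phase Activity phase, one of `"resting"`, `"walking"`, `"running"`.
#' @param sample_period_s Uniform sampling interval in seconds (default 1).
#'
#' @return A `vital_session` tibble.
#' @examples
#' raw <- load_fixture("raw_resting")
#' session_phase(raw)
#' dplyr::summarise(raw, mean_hr = mean(hr_bpm))
#' @export
vital_session <- function(data, phase = c("resting", "walking", "running"),
                          sample_period_s = 1) {
  phase <- match.arg(phase)
  stopifnot(is.data.frame(data), is.numeric(sample_period_s),
            length(sample_period_s) == 1L, sample_period_s > 0)
  data <- tibble::as_tibble(data)
  if (nrow(data) == 0L) {
    abort("no samples: a vital session must contain at least one row")
  }
  needed <- c("hr_bpm", "spo2_pct", "ambient_c", "body_c", "speed_cm_s", "alert")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0L) {
    abort(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (!"index" %in% names(data)) data$index <- seq_len(nrow(data))
  if (!"time_s" %in% names(data)) data$time_s <- (data$index - 1) * sample_period_s
  data <- dplyr::select(data, "index", "time_s", dplyr::all_of(needed))
  validate_session_rows(data)
  new_vital_session(data, phase = phase, sample_period_s = sample_period_s)
}

new_vital_session <- function(data, phase, sample_period_s) {
  structure(data,
            phase = phase,
            sample_period_s = sample_period_s,
            class = c("vital_session", class(tibble::tibble())))
}

# Row-wise invariant checks; errors name the offending 1-based row.
validate_session_rows <- function(data) {
  num_cols <- c("index", "time_s", "hr_bpm", "spo2_pct", "ambient_c",
                "body_c", "speed_cm_s", "alert")
  for (col in num_cols) {
    if (!is.numeric(data[[col]])) {
      abort(paste0("non-numeric values in column '", col, "'"))
    }
    bad <- which(is.na(data[[col]]))
    if (length(bad) > 0L) {
      abort(paste0("non-numeric or missing cell in column '", col,
                   "' at row ", bad[1]))
    }
  }
  checks <- list(
    list(ok = data$hr_bpm > 0, msg = "hr_bpm must be > 0"),
    list(ok = data$spo2_pct >= 0 & data$spo2_pct <= 100,
         msg = "spo2_pct must lie in [0, 100]"),
    list(ok = data$speed_cm_s >= 0, msg = "speed_cm_s must be >= 0"),
    list(ok = data$alert %in% c(0, 1), msg = "alert must be 0 or 1"),
    list(ok = data$time_s >= 0, msg = "time_s must be non-negative")
  )
  for (chk in checks) {
    bad <- which(!chk$ok)
    if (length(bad) > 0L) {
      abort(paste0(chk$msg, " (row ", bad[1], ")"))
    }
  }
  if (nrow(data) > 1L && any(diff(data$time_s) <= 0)) {
    bad <- which(diff(data$time_s) <= 0)[1] + 1L
    abort(paste0("time_s must be strictly increasing (row ", bad, ")"))
  }
  invisible(data)
}

#' @rdname vital_session
#' @param x A `vital_session`.
#' @export
session_phase <- function(x) attr(x, "phase", exact = TRUE)

#' @rdname vital_session
#' @export
sample_period <- function(x) attr(x, "sample_period_s", exact = TRUE)

#' @export
print.vital_session <- function(x, ...) {
  cat(sprintf("# A vital session: %d samples, phase '%s', period %g s\n",
              nrow(x), session_phase(x), sample_period(x)))
  print(tibble::as_tibble(x), ...)
  invisible(x)
}

#' Read and write vital-session CSV files
#'
#' Sessions are exchanged as plain CSV with a mandatory header naming the
#' channel columns (`hr_bpm`, `spo2_pct`, `ambient_c`, `body_c`, `speed_cm_s`,
#' `alert`, optionally `index` and `time_s`), comma separators and dot
#' decimals. The alert flag is written as an integer. Rows violating the
#' session invariants are rejected with an error naming the row.
#'
#' @param path Path to a CSV file.
#' @inheritParams vital_session
#' @return `read_session()` returns a [vital_session]; `write_session()`
#'   returns `path` invisibly.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' write_session(load_fixture("raw_walking"), tf)
#' s <- read_session(tf, phase = "walking")
#' max(s$speed_cm_s)
#' @export
read_session <- function(path, phase = c("resting", "walking", "running"),
                         sample_period_s = 1) {
  phase <- match.arg(phase)
  if (!file.exists(path)) abort(paste0("missing file: ", path))
  # non-numeric cells surface as NA here and are reported row-numbered below
  data <- suppressWarnings(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                    col_types = readr::cols(.default = readr::col_double())))
  if (nrow(data) == 0L) abort("no samples: file contains a header only or is empty")
  vital_session(data, phase = phase, sample_period_s = sample_period_s)
}

#' @rdname read_session
#' @param session A [vital_session].
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "vital_session"))
  out <- dplyr::mutate(tibble::as_tibble(session), alert = as.integer(.data$alert))
  readr::write_csv(out, path)
  invisible(path)
}
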