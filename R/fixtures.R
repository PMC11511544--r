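fixture_registry <- tibble::tribble(
  ~name,           ~phase,     ~filter,
  "raw_resting",   "resting",  "raw",
  "raw_walking",   "walking",  "raw",
  "raw_running",   "running",  "raw",
  "ma_resting",    "resting",  "moving_average",
  "ma_walking",    "walking",  "moving_average",
  "ma_running",    "running",  "moving_average",
  "gauss_resting", "resting",  "gaussian",
  "gauss_walking", "walking",  "gaussian"
)

#' Packaged reference tables
#'
#' The package ships eight 30-sample reference tables recorded from a single
#' athlete across the three activity phases: the raw streams
#' (`raw_resting`, `raw_walking`, `raw_running`), their width-5 moving-average
#' smoothed counterparts (`ma_resting`, `ma_walking`, `ma_running`) and the
#' Gaussian-smoothed resting and walking tables (`gauss_resting`,
#' `gauss_walking`). No Gaussian running table is shipped: the published
#' running table is an exact duplicate of the walking one and is treated as an
#' erratum. Values are stored exactly as printed (two decimals); the tables
#' carry no timestamps, so a 1 Hz sampling period is assumed by default.
#'
#' @param name Fixture id, one of `list_fixtures()$name`.
#' @param sample_period_s Sampling period attached to the returned session.
#' @return `load_fixture()` returns a [vital_session]; `list_fixtures()`
#'   returns a tibble with columns `name`, `phase` and `filter`.
#' @examples
#' list_fixtures()
#' run <- load_fixture("raw_running")
#' sum(run$alert)
#' @export
load_fixture <- function(name, sample_period_s = 1) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!name %in% fixture_registry$name) {
    abort(paste0("unknown fixture name '", name, "'; see list_fixtures()"))
  }
  path <- system.file("extdata", paste0(name, ".csv"), package = "vitalglove",
                      mustWork = TRUE)
  phase <- fixture_registry$phase[fixture_registry$name == name]
  read_session(path, phase = phase, sample_period_s = sample_period_s)
}

#' @rdname load_fixture
#' @export
list_fixtures <- function() {
  fixture_registry
}
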