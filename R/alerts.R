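#' Alert engine configuration
#'
#' Samples are flagged when heart rate exceeds `hr_threshold_bpm` (default
#' 150 BPM); in `"hr_and_speed"` mode the linear speed must additionally
#' exceed `speed_threshold_cm_s` (default 100 cm/s, the high-speed running
#' context). When `age_years` is given the heart-rate threshold follows the
#' age-predicted maximum heart rate, 220 - age. Each triggered alert takes
#' `refractory_s` seconds (default 2) to reset: flagged runs separated by less
#' than the refractory period merge into a single alert episode.
#'
#' @param hr_threshold_bpm Heart-rate threshold, BPM.
#' @param speed_threshold_cm_s Speed threshold, cm/s (used by
#'   `"hr_and_speed"` logic).
#' @param refractory_s Alert reset time, seconds.
#' @param age_years Optional athlete age; when given, overrides
#'   `hr_threshold_bpm` with `max_heart_rate(age_years)`.
#' @param logic `"hr_only"` (default) or `"hr_and_speed"`.
#' @return An `alert_config` object.
#' @examples
#' alert_config()
#' alert_config(age_years = 70)   # threshold 150 via 220 - age
#' @export
alert_config <- function(hr_threshold_bpm = 150, speed_threshold_cm_s = 100,
                         refractory_s = 2, age_years = NULL,
                         logic = c("hr_only", "hr_and_speed")) {
  logic <- match.arg(logic)
  if (!is.null(age_years)) hr_threshold_bpm <- max_heart_rate(age_years)
  stopifnot(hr_threshold_bpm > 0, speed_threshold_cm_s > 0, refractory_s >= 0)
  structure(list(hr_threshold_bpm = hr_threshold_bpm,
                 speed_threshold_cm_s = speed_threshold_cm_s,
                 refractory_s = refractory_s,
                 age_years = age_years,
                 logic = logic),
            class = "alert_config")
}

#' @export
print.alert_config <- function(x, ...) {
  cat(sprintf("<alert_config> HR > %g BPM%s, refractory %g s (%s)\n",
              x$hr_threshold_bpm,
              if (x$logic == "hr_and_speed")
                sprintf(" & speed > %g cm/s", x$speed_threshold_cm_s) else "",
              x$refractory_s, x$logic))
  invisible(x)
}

#' Age-predicted maximum heart rate
#'
#' The conventional 220 - age rule used to set a safe exercise heart-rate
#' ceiling.
#'
#' @param age_years Age in whole years, in (0, 120].
#' @return Maximum heart rate in BPM.
#' @examples
#' max_heart_rate(20)
#' @export
max_heart_rate <- function(age_years) {
  stopifnot(is.numeric(age_years), length(age_years) == 1L)
  if (age_years <= 0 || age_years > 120) {
    abort("age_years must lie in (0, 120]")
  }
  220 - age_years
}

#' Flag above-threshold samples
#'
#' Instantaneous per-sample alert flags: 1 where the configured threshold
#' logic fires, 0 elsewhere. Flags are computed on whatever session the
#' caller passes — raw or smoothed — since the engine is signal-agnostic.
#'
#' @param session A [vital_session].
#' @param config An [alert_config].
#' @return Integer vector of 0/1 flags, one per sample.
#' @examples
#' run <- load_fixture("raw_running")
#' which(flag_series(run) == 1)   # rows 16, 17, 23, 24
#' @export
flag_series <- function(session, config = alert_config()) {
  stopifnot(inherits(session, "vital_session"), inherits(config, "alert_config"))
  hit <- session$hr_bpm > config$hr_threshold_bpm
  if (config$logic == "hr_and_speed") {
    hit <- hit & session$speed_cm_s > config$speed_threshold_cm_s
  }
  as.integer(hit)
}

#' Group flags into alert episodes
#'
#' Consecutive flagged samples form one episode; flagged runs separated by a
#' gap shorter than `merge_gap_s` seconds (the alert reset time) also merge.
#' Episodes are returned in start order.
#'
#' @param flags Integer/logical vector of per-sample flags.
#' @param sample_period_s Sampling period in seconds.
#' @param merge_gap_s Gaps strictly shorter than this merge adjacent runs.
#' @param hr_bpm Optional heart-rate vector (same length as `flags`) used to
#'   report the peak heart rate inside each episode.
#' @return A tibble with columns `start_index`, `end_index`, `n_samples` and
#'   `peak_hr_bpm` (NA when `hr_bpm` is not supplied); zero rows when nothing
#'   is flagged.
#' @examples
#' run <- load_fixture("raw_running")
#' alert_episodes(flag_series(run), sample_period_s = 1, merge_gap_s = 2,
#'                hr_bpm = run$hr_bpm)
#' @export
alert_episodes <- function(flags, sample_period_s = 1, merge_gap_s = 2,
                           hr_bpm = NULL) {
  stopifnot(merge_gap_s >= 0, sample_period_s > 0)
  flags <- as.integer(as.logical(flags))
  empty <- tibble::tibble(start_index = integer(), end_index = integer(),
                          n_samples = integer(), peak_hr_bpm = double())
  idx <- which(flags == 1L)
  if (length(idx) == 0L) return(empty)
  # consecutive samples continue an episode; a gap of unflagged samples
  # shorter than the reset time merges the neighbouring runs
  new_episode <- c(TRUE, (diff(idx) > 1L) &
                     ((diff(idx) - 1L) * sample_period_s >= merge_gap_s))
  ep_id <- cumsum(new_episode)
  purrr::map_dfr(split(idx, ep_id), function(ii) {
    tibble::tibble(
      start_index = min(ii), end_index = max(ii),
      n_samples = max(ii) - min(ii) + 1L,
      peak_hr_bpm = if (is.null(hr_bpm)) NA_real_ else max(hr_bpm[min(ii):max(ii)])
    )
  })
}

#' Vibration actuator contract
#'
#' Pure state-transition function standing in for the glove's vibration
#' motor: returns `"start"` on an inactive-to-active transition, `"stop"` on
#' active-to-inactive, `"none"` otherwise. Hardware control is out of scope;
#' this is the contract boundary.
#'
#' @param previous_active,episode_active Logical alert-episode states before
#'   and after the transition.
#' @return One of `"start"`, `"stop"`, `"none"`.
#' @examples
#' actuate(FALSE, TRUE)
#' @export
actuate <- function(previous_active, episode_active) {
  stopifnot(is.logical(previous_active), is.logical(episode_active))
  if (!previous_active && episode_active) "start"
  else if (previous_active && !episode_active) "stop"
  else "none"
}
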