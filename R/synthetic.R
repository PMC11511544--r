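#' Per-phase generator parameters
#'
#' Level-and-noise description of one activity phase, tuned to the packaged
#' reference tables: resting heart rate around 77 BPM with a ~0.5 cm/s
#' gyroscope-drift speed floor; walking heart rate around 80 BPM with speeds
#' up to ~60 cm/s; running heart rate ramping toward ~155-160 BPM (so the
#' default 150 BPM alert threshold is reachable) with speeds of roughly
#' 50-290 cm/s. Speed is not drawn directly: the generator draws a gyroscope
#' trace (deg/s) whose magnitude corresponds to the target speed through the
#' cross-product arm model, plus an additive drift noise floor, and converts
#' it with [speed_series()]. Body temperature follows the tables' per-phase
#' bases (slightly lower while walking than at rest) without asserting a
#' physiological mechanism. Artifact spikes are multiplicative single-sample
#' events (sensor-motion false peaks) applied to the heart-rate channel;
#' the resting tables are stable, so resting defaults to no spikes.
#'
#' @param phase `"resting"`, `"walking"` or `"running"`.
#' @param ... Named overrides of any default field.
#' @return A `phase_params` list with fields `phase`, `duration_s`,
#'   `hr_base_bpm`, `hr_sd`, `hr_ramp_bpm_per_s`, `spo2_base_pct`,
#'   `spo2_jitter`, `ambient_c_base`, `ambient_drift_per_s`, `body_c_base`,
#'   `body_drift_per_s`, `speed_base_cm_s`, `speed_sd_cm_s`,
#'   `gyro_noise_dps`, `spike_rate_per_min`, `spike_gain`.
#' @examples
#' phase_params("resting")
#' phase_params("running", duration_s = 120)
#' @export
phase_params <- function(phase = c("resting", "walking", "running"), ...) {
  phase <- match.arg(phase)
  defaults <- switch(phase,
    resting = list(
      duration_s = 300, hr_base_bpm = 77, hr_sd = 2.5, hr_ramp_bpm_per_s = 0,
      spo2_base_pct = 97, spo2_jitter = 0.03,
      ambient_c_base = 32.2, ambient_drift_per_s = 0.015,
      body_c_base = 35.7, body_drift_per_s = 0,
      speed_base_cm_s = 0, speed_sd_cm_s = 0, gyro_noise_dps = 1,
      spike_rate_per_min = 0, spike_gain = 1
    ),
    walking = list(
      duration_s = 300, hr_base_bpm = 80, hr_sd = 12, hr_ramp_bpm_per_s = 0,
      spo2_base_pct = 96, spo2_jitter = 0.05,
      ambient_c_base = 33.1, ambient_drift_per_s = -0.025,
      body_c_base = 34.3, body_drift_per_s = 0,
      speed_base_cm_s = 30, speed_sd_cm_s = 15, gyro_noise_dps = 2,
      spike_rate_per_min = 0.4, spike_gain = 1.6
    ),
    running = list(
      duration_s = 300, hr_base_bpm = 85, hr_sd = 8, hr_ramp_bpm_per_s = 0.25,
      spo2_base_pct = 96, spo2_jitter = 0.05,
      ambient_c_base = 32.5, ambient_drift_per_s = -0.01,
      body_c_base = 35.4, body_drift_per_s = 0,
      speed_base_cm_s = 160, speed_sd_cm_s = 60, gyro_noise_dps = 4,
      spike_rate_per_min = 0.6, spike_gain = 1.3
    )
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown) > 0L) {
    abort(paste0("unknown phase_params field(s): ", paste(unknown, collapse = ", ")))
  }
  p <- utils::modifyList(defaults, over)
  stopifnot(p$duration_s > 0, p$hr_base_bpm > 0, p$hr_sd >= 0,
            p$spo2_base_pct >= 0, p$spo2_base_pct <= 100,
            p$speed_base_cm_s >= 0, p$speed_sd_cm_s >= 0,
            p$gyro_noise_dps >= 0, p$spike_rate_per_min >= 0, p$spike_gain > 0)
  structure(c(list(phase = phase), p), class = "phase_params")
}

# run code under a caller-supplied seed without disturbing the global stream
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Inject single-sample artifact spikes
#'
#' Places `rpois(1, rate_per_min * minutes)` spikes uniformly at random over
#' the series and multiplies the affected samples by `gain`, emulating the
#' transient false peaks caused by sensor movement. Deterministic for a given
#' `seed`.
#'
#' @param series Numeric vector.
#' @param rate_per_min Expected spikes per minute of signal.
#' @param gain Multiplicative spike amplitude (1 = no change).
#' @param sample_period_s Sampling period in seconds.
#' @param seed Optional integer seed; `NULL` uses (and advances) the current
#'   RNG stream.
#' @return Numeric vector with spikes applied.
#' @examples
#' x <- rep(95, 300)
#' spiked <- inject_spikes(x, rate_per_min = 1, gain = 1.5, seed = 7)
#' sum(spiked != x)
#' @export
inject_spikes <- function(series, rate_per_min, gain, sample_period_s = 1,
                          seed = NULL) {
  stopifnot(is.numeric(series), rate_per_min >= 0, gain > 0)
  if (rate_per_min == 0 || gain == 1 || length(series) == 0L) return(series)
  with_local_seed(seed, {
    minutes <- length(series) * sample_period_s / 60
    n_spikes <- min(rpois(1L, rate_per_min * minutes), length(series))
    if (n_spikes > 0L) {
      at <- sample.int(length(series), n_spikes)
      series[at] <- series[at] * gain
    }
    series
  })
}

simulate_phase <- function(params, sample_period_s, config, arm) {
  n <- max(1L, round(params$duration_s / sample_period_s))
  t <- (seq_len(n) - 1) * sample_period_s

  hr <- params$hr_base_bpm + params$hr_ramp_bpm_per_s * t +
    rnorm(n, 0, params$hr_sd)
  hr <- inject_spikes(hr, params$spike_rate_per_min, params$spike_gain,
                      sample_period_s)
  hr <- pmax(hr, 30)

  # SpO2: integer plateau with rare +/-1 steps, clipped near the base
  steps <- sample(c(-1L, 0L, 1L), n, replace = TRUE,
                  prob = c(params$spo2_jitter / 2, 1 - params$spo2_jitter,
                           params$spo2_jitter / 2))
  spo2 <- params$spo2_base_pct + pmin(pmax(cumsum(steps), -2L), 2L)
  spo2 <- pmin(pmax(round(spo2), 0), 100)

  ambient <- params$ambient_c_base + params$ambient_drift_per_s * t +
    rnorm(n, 0, 0.02)
  body <- params$body_c_base + params$body_drift_per_s * t + rnorm(n, 0, 0.1)

  # speed through the kinematics path: target speed -> gyro magnitude (deg/s)
  r_mag <- sqrt(sum(as.numeric(arm)^2))
  to_dps <- function(cm_s) cm_s / (100 * r_mag) * 180 / pi
  gyro_y <- rnorm(n, to_dps(params$speed_base_cm_s),
                  to_dps(params$speed_sd_cm_s)) +
    rnorm(n, 0, params$gyro_noise_dps)
  gyro_z <- rnorm(n, 0, params$gyro_noise_dps)
  gyro_x <- rnorm(n, 0, params$gyro_noise_dps)
  trace <- tibble::tibble(gyro_x = gyro_x, gyro_y = gyro_y, gyro_z = gyro_z)
  speed <- speed_series(trace, arm)$speed_cm_s

  df <- tibble::tibble(
    index = seq_len(n), time_s = t, hr_bpm = hr, spo2_pct = spo2,
    ambient_c = ambient, body_c = body, speed_cm_s = speed, alert = 0
  )
  session <- vital_session(df, phase = params$phase,
                           sample_period_s = sample_period_s)
  session$alert <- as.numeric(flag_series(session, config))
  session
}

#' Generate synthetic three-phase monitoring sessions
#'
#' Seedable emulation of a glove recording: per-sample channels are drawn
#' from the per-phase level/noise model in [phase_params()], speed is derived
#' from a simulated gyroscope trace through the cross-product kinematics, and
#' the alert column is pre-populated with the default threshold engine run on
#' the generated channels. Identical seeds give identical sessions; the
#' global RNG state is left untouched.
#'
#' @param params A `phase_params` object or a list of them (default: the
#'   three standard phases).
#' @param sample_period_s Sampling period in seconds (default 1).
#' @param seed Integer seed.
#' @param config [alert_config()] used to populate the alert column.
#' @param arm [arm_model()] used for the gyroscope-to-speed conversion.
#' @return A named list of [vital_session]s, one per phase (a single
#'   `vital_session` if `params` is a single `phase_params`).
#' @examples
#' s <- generate_session(phase_params("resting", duration_s = 60), seed = 1)
#' mean(s$speed_cm_s)  # small but nonzero: gyro drift floor
#' @export
generate_session <- function(params = list(phase_params("resting"),
                                           phase_params("walking"),
                                           phase_params("running")),
                             sample_period_s = 1, seed,
                             config = alert_config(), arm = arm_model()) {
  single <- inherits(params, "phase_params")
  if (single) params <- list(params)
  if (length(params) == 0L) abort("empty params: nothing to generate")
  stopifnot(all(purrr::map_lgl(params, inherits, "phase_params")))
  with_local_seed(seed, {
    out <- purrr::map(params, simulate_phase,
                      sample_period_s = sample_period_s,
                      config = config, arm = arm)
    names(out) <- purrr::map_chr(params, "phase")
    if (single) out[[1]] else out
  })
}
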