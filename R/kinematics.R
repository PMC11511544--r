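#' Arm model for gyroscope-to-speed conversion
#'
#' During running the forearm sweeps part of a circle about the elbow, so the
#' elbow is taken as the rotation origin and the sensor sits at the end of a
#' fixed position vector `r`. Small changes in the effective radius over a
#' stride are neglected: `r` is one configuration parameter per session. The
#' default radius of 0.25 m is a typical adult forearm length.
#'
#' @param r_m Numeric length-3 position vector (metres) from the elbow origin
#'   to the sensor.
#' @return An `arm_model` object (named numeric triplet).
#' @examples
#' arm_model()
#' arm_model(c(0.3, 0, 0))
#' @export
arm_model <- function(r_m = c(0.25, 0, 0)) {
  stopifnot(is.numeric(r_m), length(r_m) == 3L, all(is.finite(r_m)))
  if (sqrt(sum(r_m^2)) <= 0) abort("arm radius |r| must be > 0")
  structure(setNames(as.numeric(r_m), c("rx", "ry", "rz")), class = "arm_model")
}

#' Convert gyroscope angular velocity to linear velocity and speed
#'
#' The sensor reports angular velocity in degrees/s; `deg_to_rad()` converts
#' each axis to rad/s. For a rigid rotation about the elbow, the linear
#' velocity at the sensor is the cross product `v = omega x r`, with
#' components `vx = wy*rz - wz*ry`, `vy = wz*rx - wx*rz`, `vz = wx*ry - wy*rx`,
#' and the linear speed is the Euclidean magnitude of `v`. Speeds are reported
#' in cm/s rather than m/s so that the small spurious speed floor caused by
#' gyroscope drift at rest remains visible instead of rounding to zero.
#'
#' @param omega_dps,omega_rad_s Numeric length-3 angular velocity (deg/s or
#'   rad/s).
#' @param arm An [arm_model].
#' @return `deg_to_rad()` a rad/s triplet; `linear_velocity()` a named m/s
#'   triplet `(vx, vy, vz)`; `linear_speed()` a non-negative scalar in cm/s.
#' @examples
#' w <- deg_to_rad(c(0, 0, 180))   # half a turn per second about z
#' v <- linear_velocity(w, arm_model())
#' linear_speed(v)                 # cm/s
#' @export
deg_to_rad <- function(omega_dps) {
  stopifnot(is.numeric(omega_dps), all(is.finite(omega_dps)))
  omega_dps * pi / 180
}

#' @rdname deg_to_rad
#' @export
linear_velocity <- function(omega_rad_s, arm = arm_model()) {
  stopifnot(is.numeric(omega_rad_s), length(omega_rad_s) == 3L,
            all(is.finite(omega_rad_s)))
  if (!inherits(arm, "arm_model")) arm <- arm_model(arm)
  w <- as.numeric(omega_rad_s)
  r <- as.numeric(arm)
  c(vx = w[2] * r[3] - w[3] * r[2],
    vy = w[3] * r[1] - w[1] * r[3],
    vz = w[1] * r[2] - w[2] * r[1])
}

#' @rdname deg_to_rad
#' @param v Numeric length-3 linear velocity in m/s.
#' @export
linear_speed <- function(v) {
  stopifnot(is.numeric(v), length(v) == 3L, all(is.finite(v)))
  100 * sqrt(sum(v^2))
}

#' Linear speed trace from a gyroscope trace
#'
#' Applies the cross-product model sample by sample: converts each gyroscope
#' reading from deg/s to rad/s, forms `v = omega x r` about the elbow and
#' returns the speed magnitude in cm/s.
#'
#' @param imu_trace Data frame with numeric columns `gyro_x`, `gyro_y`,
#'   `gyro_z` in deg/s (one row per sample).
#' @param arm An [arm_model].
#' @return The input tibble with a `speed_cm_s` column appended.
#' @examples
#' trace <- tibble::tibble(gyro_x = 0, gyro_y = 0, gyro_z = rep(57.29578, 5))
#' speed_series(trace)$speed_cm_s  # ~25 cm/s for |omega| = 1 rad/s, r = 0.25 m
#' @export
speed_series <- function(imu_trace, arm = arm_model()) {
  stopifnot(is.data.frame(imu_trace))
  if (nrow(imu_trace) == 0L) abort("empty IMU trace")
  needed <- c("gyro_x", "gyro_y", "gyro_z")
  if (!all(needed %in% names(imu_trace))) {
    abort("IMU trace needs columns gyro_x, gyro_y, gyro_z (deg/s)")
  }
  imu_trace <- tibble::as_tibble(imu_trace)
  omega <- deg_to_rad(as.matrix(imu_trace[, needed]))
  dplyr::mutate(imu_trace, speed_cm_s = purrr::map_dbl(
    seq_len(nrow(imu_trace)),
    function(i) linear_speed(linear_velocity(omega[i, ], arm))
  ))
}
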