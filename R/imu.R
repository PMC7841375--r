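#' Bundle of raw IMU channels
#'
#' Holds the sensor-frame specific force (accelerometer), sensor-frame
#' angular velocity (gyroscope) and an estimate of the sensor-to-earth
#' orientation, all on the same clock. The orientation estimate may be
#' error-bearing; reconstruction quality is studied by composing the true
#' orientation with a simulated error series.
#'
#' @param accel [kin_series()] of kind `acceleration`: specific force in the
#'   sensor frame, gravity included, m/s^2.
#' @param gyro [kin_series()] of kind `angular_velocity`: sensor-frame
#'   angular velocity, rad/s.
#' @param orientation_estimate optional [rot_series()] estimating the
#'   sensor-to-earth rotation per sample.
#' @return an object of class `imu_reading`.
#' @export
imu_reading <- function(accel, gyro, orientation_estimate = NULL) {
  stopifnot(inherits(accel, "kin_series"), inherits(gyro, "kin_series"))
  if (n_samples(accel) != n_samples(gyro) || accel$fs != gyro$fs) {
    stop("accel and gyro must share N and fs", call. = FALSE)
  }
  if (!is.null(orientation_estimate)) {
    stopifnot(inherits(orientation_estimate, "rot_series"))
    if (n_samples(orientation_estimate) != n_samples(accel) ||
        orientation_estimate$fs != accel$fs) {
      stop("orientation estimate must share N and fs with the channels", call. = FALSE)
    }
  }
  structure(
    list(accel = accel, gyro = gyro, orientation_estimate = orientation_estimate),
    class = "imu_reading"
  )
}

#' @export
print.imu_reading <- function(x, ...) {
  cat(sprintf(
    "<imu_reading> %d samples @ %g Hz (orientation estimate: %s)\n",
    n_samples(x$accel), x$accel$fs,
    if (is.null(x$orientation_estimate)) "none" else "present"
  ))
  invisible(x)
}

#' Forward model: what an IMU measures for a known movement
#'
#' For a movement whose body frame is fixed with respect to the earth frame,
#' an ideal (noise-free) IMU with sensor-to-earth orientation `R(t)` measures
#' specific force `R'(x'' + g)` and angular velocity `R' omega` in its own
#' frame. This is the exact inverse of [reconstruct_linear()] /
#' [reconstruct_angular()] when the orientation estimate equals the true
#' orientation.
#'
#' @param truth a [sim_movement] (see [via_point_movement()]) or any list with
#'   `acceleration` and `velocity` [kin_series()] elements.
#' @param sensor_orientation [rot_series()]: true sensor-to-earth rotation.
#' @param g a [gravity_vector()].
#' @param omega optional [kin_series()] of kind `angular_velocity` giving the
#'   true earth-frame angular velocity. By default the movement's velocity
#'   values are reused as angular velocity (in rad/s), the convention used to
#'   study rotational movements with the same simulated trajectories.
#' @param orientation_estimate [rot_series()] stored in the reading as the
#'   orientation estimate; defaults to the true `sensor_orientation`
#'   (i.e. perfect orientation reconstruction).
#' @return an [imu_reading()].
#' @export
forward_measure <- function(truth, sensor_orientation, g = gravity_vector(),
                            omega = NULL,
                            orientation_estimate = sensor_orientation) {
  accel <- truth$acceleration
  stopifnot(inherits(accel, "kin_series"), inherits(sensor_orientation, "rot_series"))
  if (is.null(omega)) {
    omega <- kin_series(truth$velocity$values, fs = truth$velocity$fs,
                        kind = "angular_velocity")
  }
  rt <- rot_transpose(sensor_orientation)
  sp_force <- sweep(accel$values, 2L, unclass(g), `+`)
  accel_s <- kin_series(.rot_apply_mat(rt, sp_force), fs = accel$fs,
                        kind = "acceleration")
  gyro_s <- apply_rotation(omega, rt)
  imu_reading(accel_s, gyro_s, orientation_estimate = orientation_estimate)
}

#' Earth-frame linear kinematics from an IMU reading
#'
#' Rotates the accelerometer channel into the earth frame with the
#' orientation estimate, removes gravity and integrates once:
#' `a_hat = R_hat a_sensor - g`, `v_hat = integral of a_hat` (zero initial
#' velocity, justified for discrete movements that start at rest). When the
#' estimate is wrong by `dR`, the reconstruction error is
#' `delta_a = (dR - I)(x'' + g)`, and its running integral `delta_v` drifts —
#' the mechanism that makes velocity-based smoothness unreliable from IMUs.
#'
#' @param reading an [imu_reading()] with an orientation estimate.
#' @param g a [gravity_vector()].
#' @param truth optional ground-truth movement (a [sim_movement] or list with
#'   an `acceleration` [kin_series()]); when given, the error series
#'   `delta_a` and `delta_v` are populated.
#' @return an object of class `reconstructed_kinematics` with elements
#'   `accel_earth`, `velocity_earth` and (when truth is known) `delta_a`,
#'   `delta_v`.
#' @export
reconstruct_linear <- function(reading, g = gravity_vector(), truth = NULL) {
  stopifnot(inherits(reading, "imu_reading"))
  if (is.null(reading$orientation_estimate)) {
    stop("reconstruction requires an orientation estimate", call. = FALSE)
  }
  rhat <- reading$orientation_estimate
  accel_earth <- kin_series(
    sweep(.rot_apply_mat(rhat, reading$accel$values), 2L, unclass(g)),
    fs = reading$accel$fs, kind = "acceleration"
  )
  velocity_earth <- integrate_cumulative(accel_earth, c(0, 0, 0))
  delta_a <- delta_v <- NULL
  if (!is.null(truth)) {
    delta_a <- kin_series(accel_earth$values - truth$acceleration$values,
                          fs = accel_earth$fs, kind = "acceleration")
    delta_v <- integrate_cumulative(delta_a, c(0, 0, 0))
  }
  structure(
    list(accel_earth = accel_earth, velocity_earth = velocity_earth,
         omega_earth = NULL, delta_a = delta_a, delta_v = delta_v,
         delta_omega = NULL),
    class = "reconstructed_kinematics"
  )
}

#' Earth-frame angular velocity from an IMU reading
#'
#' `omega_hat = R_hat w_sensor`. Rotation preserves the per-sample norm, so
#' the angular *speed* profile — and with it SPARC — is exact no matter how
#' wrong the orientation estimate is; only direction errors
#' `delta_omega = (dR - I) omega` appear, which is what degrades LDLJ-V.
#'
#' @param reading an [imu_reading()] with an orientation estimate.
#' @param truth_omega optional [kin_series()] of the true earth-frame angular
#'   velocity; when given, `delta_omega` is populated.
#' @return a `reconstructed_kinematics` object with `omega_earth` (and
#'   `delta_omega` when truth is known).
#' @export
reconstruct_angular <- function(reading, truth_omega = NULL) {
  stopifnot(inherits(reading, "imu_reading"))
  if (is.null(reading$orientation_estimate)) {
    stop("reconstruction requires an orientation estimate", call. = FALSE)
  }
  omega_earth <- apply_rotation(reading$gyro, reading$orientation_estimate)
  delta_omega <- NULL
  if (!is.null(truth_omega)) {
    delta_omega <- kin_series(omega_earth$values - truth_omega$values,
                              fs = omega_earth$fs, kind = "angular_velocity")
  }
  structure(
    list(accel_earth = NULL, velocity_earth = NULL, omega_earth = omega_earth,
         delta_a = NULL, delta_v = NULL, delta_omega = delta_omega),
    class = "reconstructed_kinematics"
  )
}

#' Sensor-to-gravity ratio (SGR)
#'
#' `SGR = (1 / |g|) * sqrt( (1 / (t2 - t1)) * integral ||a_sensor||^2 dt )`:
#' the RMS of the sensor-frame specific force in units of gravity. A static
#' sensor gives SGR = 1, a free-falling one SGR = 0, and values above 1
#' indicate that the movement's own linear acceleration contributes
#' appreciably to the reading. SGR depends only on the norm of the specific
#' force, so it is invariant to the (unknown) sensor orientation and can be
#' computed from raw accelerometer data.
#'
#' @param accel_sensor [kin_series()] of kind `acceleration`: sensor-frame
#'   specific force, gravity included.
#' @param g a [gravity_vector()].
#' @return a nonnegative scalar.
#' @export
sgr <- function(accel_sensor, g = gravity_vector()) {
  stopifnot(inherits(accel_sensor, "kin_series"))
  if (accel_sensor$kind != "acceleration") {
    stop("SGR is defined on sensor-frame acceleration", call. = FALSE)
  }
  gmag <- sqrt(sum(unclass(g)^2))
  ms <- .trapz(norm_series(accel_sensor)^2, accel_sensor$fs) / duration(accel_sensor)
  sqrt(ms) / gmag
}
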