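#' @name sim_movement
#' @title Simulated minimum-jerk movement bundle
#' @description A `sim_movement` bundles the ground-truth kinematics of a
#'   simulated discrete movement: `position`, `velocity`, `acceleration` and
#'   `jerk` [kin_series()] evaluated analytically from a piecewise
#'   minimum-jerk construction, plus `duration_s`, `n_via`, `amplitude_m`
#'   (total path length in metres), `seed`, and the generating `segments`
#'   specification (waypoints and per-segment duration fractions) from which
#'   the trajectory can be re-evaluated exactly, e.g. by [time_scale()].
#'   Every simulated movement is discrete: it starts and ends at rest, so the
#'   time integral of acceleration over the whole movement is zero.
NULL

# minimum-jerk basis in normalised time tau in [0, 1]
.mj_pos <- function(tau) 10 * tau^3 - 15 * tau^4 + 6 * tau^5
.mj_vel <- function(tau) 30 * tau^2 - 60 * tau^3 + 30 * tau^4
.mj_acc <- function(tau) 60 * tau - 180 * tau^2 + 120 * tau^3
.mj_jrk <- function(tau) 60 - 360 * tau + 360 * tau^2

# evaluate a piecewise minimum-jerk trajectory through `waypoints`
# (M x 3, zero velocity and acceleration at every waypoint) with segment
# durations `seg_dur` (length M - 1) on a uniform clock at `fs`
.eval_piecewise_min_jerk <- function(waypoints, seg_dur, fs) {
  total <- sum(seg_dur)
  n <- round(total * fs) + 1L
  t <- seq(0L, n - 1L) / fs
  breaks <- cumsum(seg_dur)
  idx <- pmin(findInterval(t, c(0, breaks), all.inside = TRUE), length(seg_dur))
  start_t <- c(0, breaks)[idx]
  d <- seg_dur[idx]
  tau <- pmin(pmax((t - start_t) / d, 0), 1)
  p0 <- waypoints[idx, , drop = FALSE]
  dp <- waypoints[idx + 1L, , drop = FALSE] - p0
  pos <- p0 + dp * .mj_pos(tau)
  vel <- dp * (.mj_vel(tau) / d)
  acc <- dp * (.mj_acc(tau) / d^2)
  jrk <- dp * (.mj_jrk(tau) / d^3)
  list(
    position = kin_series(pos, fs, "position"),
    velocity = kin_series(vel, fs, "velocity"),
    acceleration = kin_series(acc, fs, "acceleration"),
    jerk = kin_series(jrk, fs, "jerk"),
    duration_s = total
  )
}

.new_sim_movement <- function(kin, n_via, amplitude_m, seed, waypoints, seg_dur) {
  structure(
    c(kin, list(
      n_via = n_via, amplitude_m = amplitude_m, seed = seed,
      segments = list(waypoints = waypoints, frac_durations = seg_dur / sum(seg_dur))
    )),
    class = "sim_movement"
  )
}

#' @export
print.sim_movement <- function(x, ...) {
  cat(sprintf(
    "<sim_movement> %d via-point(s), T = %g s, path %.3g m, fs = %g Hz, seed %s\n",
    x$n_via, x$duration_s, x$amplitude_m, x$velocity$fs,
    if (is.na(x$seed)) "-" else x$seed
  ))
  invisible(x)
}

#' Single minimum-jerk point-to-point movement
#'
#' The quintic minimum-jerk profile `x(tau) = A (10 tau^3 - 15 tau^4 +
#' 6 tau^5)`, `tau = t / T`, along a straight line. Velocity and acceleration
#' vanish at both ends; the peak speed is `1.875 A / T` at mid-movement and
#' the integrated squared jerk is `720 A^2 / T^5`.
#'
#' @param amplitude movement amplitude A in metres (> 0).
#' @param duration movement duration T in seconds (> 0).
#' @param fs sampling frequency in Hz.
#' @param direction 3-vector giving the movement direction (normalised
#'   internally).
#' @return a [sim_movement].
#' @examples
#' mov <- min_jerk_segment(0.15, 1, fs = 100)
#' max(norm_series(mov$velocity))  # 1.875 * 0.15
#' @export
min_jerk_segment <- function(amplitude, duration, fs = 100,
                             direction = c(1, 0, 0)) {
  stopifnot(amplitude > 0, duration > 0, fs > 0, length(direction) == 3L)
  dir <- direction / sqrt(sum(direction^2))
  waypoints <- rbind(c(0, 0, 0), amplitude * dir)
  kin <- .eval_piecewise_min_jerk(waypoints, duration, fs)
  .new_sim_movement(kin, n_via = 0L, amplitude_m = amplitude, seed = NA_integer_,
                    waypoints = waypoints, seg_dur = duration)
}

#' Seeded minimum-jerk movement through random via-points
#'
#' Builds a discrete movement of `n_via + 1` minimum-jerk segments joined at
#' seeded random intermediate points, with zero velocity and acceleration at
#' every via-point (each via-point is a full submovement boundary). Segment
#' durations are a seeded random partition of the total duration; waypoints
#' are drawn uniformly in a cubic workspace and the whole path is rescaled so
#' that the total path length equals `amplitude`. More via-points means more
#' submovements, hence lower smoothness under every measure.
#'
#' @param n_via number of intermediate via-points (>= 1).
#' @param fs sampling frequency in Hz (default 100).
#' @param seed integer seed; the trajectory is a deterministic function of
#'   `(seed, parameters)`.
#' @param amplitude total path length in metres (default 0.15).
#' @param duration total movement duration in seconds (default 1).
#' @param min_segment optional minimum segment duration in seconds. By
#'   default 0.1 s, reduced to half of the equal share
#'   `duration / (2 (n_via + 1))` when 0.1 s is infeasible for the requested
#'   number of segments. An explicit infeasible value raises an error.
#'   Random segment durations are quantised to 0.02 s so that submovement
#'   boundaries stay on the sample grid at the study sampling rate and
#'   durations, which keeps the trapezoidal discrete-movement closure
#'   (zero final integrated velocity) exact.
#' @param waypoints optional explicit `(n_via + 2) x 3` waypoint matrix
#'   (start, via-points, end) overriding the random draw; it is still
#'   rescaled to the requested path length.
#' @param seg_durations optional explicit segment durations (length
#'   `n_via + 1`), overriding the random partition; rescaled to sum to
#'   `duration`.
#' @return a [sim_movement].
#' @examples
#' m <- via_point_movement(2, seed = 7)
#' m$duration_s
#' @export
via_point_movement <- function(n_via, fs = 100, seed = 1L, amplitude = 0.15,
                               duration = 1, min_segment = NULL,
                               waypoints = NULL, seg_durations = NULL) {
  stopifnot(n_via >= 1, fs > 0, amplitude > 0, duration > 0)
  n_seg <- n_via + 1L
  if (!is.null(min_segment) && n_seg * min_segment > duration) {
    stop(sprintf(
      "infeasible partition: %d segments of >= %g s exceed the %g s total",
      n_seg, min_segment, duration
    ), call. = FALSE)
  }
  floor_s <- min_segment %||% min(0.1, duration / (2 * n_seg))
  quantum <- 0.02
  units_total <- round(duration / quantum)
  min_units <- max(2L, floor(floor_s / quantum))
  if (n_seg * min_units > units_total) {
    stop(sprintf(
      "infeasible partition: %d segments of >= %g s exceed the %g s total",
      n_seg, min_units * quantum, duration
    ), call. = FALSE)
  }
  withr::with_seed(seed, {
    if (is.null(waypoints)) {
      waypoints <- rbind(
        c(0, 0, 0),
        matrix(stats::runif(3L * (n_via + 1L), 0, amplitude), ncol = 3L)
      )
    } else {
      waypoints <- as.matrix(waypoints)
      stopifnot(nrow(waypoints) == n_seg + 1L, ncol(waypoints) == 3L)
    }
    if (is.null(seg_durations)) {
      # random partition on the quantised grid by the largest-remainder rule
      u <- stats::runif(n_seg, 0.5, 1.5)
      spare <- units_total - n_seg * min_units
      ideal <- spare * u / sum(u)
      k <- floor(ideal)
      left <- spare - sum(k)
      if (left > 0) {
        top_up <- order(ideal - k, decreasing = TRUE)[seq_len(left)]
        k[top_up] <- k[top_up] + 1L
      }
      seg_durations <- (min_units + k) * quantum
    } else {
      stopifnot(length(seg_durations) == n_seg, all(seg_durations > 0))
      seg_durations <- seg_durations / sum(seg_durations) * duration
    }
  })
  seg_len <- sqrt(rowSums((waypoints[-1L, , drop = FALSE] -
                             waypoints[-nrow(waypoints), , drop = FALSE])^2))
  if (any(seg_len == 0)) stop("degenerate via-point draw: coincident waypoints", call. = FALSE)
  waypoints <- waypoints * (amplitude / sum(seg_len))
  kin <- .eval_piecewise_min_jerk(waypoints, seg_durations, fs)
  .new_sim_movement(kin, n_via = as.integer(n_via), amplitude_m = amplitude,
                    seed = as.integer(seed), waypoints = waypoints,
                    seg_dur = seg_durations)
}

#' Time-scale a simulated movement
#'
#' Stretches the movement clock to a new total duration `T` while keeping the
#' spatial path unchanged: velocity scales by `1/T`, acceleration by `1/T^2`
#' and jerk by `1/T^3` (relative to a 1 s base movement). The trajectory is
#' re-evaluated analytically from the stored segment specification, so the
#' scaling is exact at every sample.
#'
#' @param movement a [sim_movement].
#' @param T new total duration in seconds.
#' @return a [sim_movement] with `duration_s = T`.
#' @export
time_scale <- function(movement, T) {
  stopifnot(inherits(movement, "sim_movement"), T > 0)
  seg <- movement$segments
  kin <- .eval_piecewise_min_jerk(seg$waypoints, seg$frac_durations * T,
                                  movement$velocity$fs)
  .new_sim_movement(kin, n_via = movement$n_via,
                    amplitude_m = movement$amplitude_m, seed = movement$seed,
                    waypoints = seg$waypoints, seg_dur = seg$frac_durations * T)
}

#' Stochastic orientation reconstruction error series
#'
#' Simulates the time-varying mismatch `dR(t)` between an estimated and the
#' true sensor orientation as `dR(t) = Rz(alpha) Ry(beta) Rx(gamma)`. Each
#' Euler angle is an independent realisation of Brownian noise (cumulative
#' sum of white Gaussian noise) smoothed by a centred moving-average filter
#' of 0.5 s, then rescaled per axis so that `max |angle| = theta_max`. The
#' white-noise variance before scaling is immaterial (the rescale absorbs
#' it); the moving average is edge-truncated.
#'
#' @param theta_max_deg maximum absolute Euler angle in degrees (>= 0);
#'   `0` yields the identity series.
#' @param duration series duration in seconds.
#' @param fs sampling frequency in Hz.
#' @param seed integer seed; output is a deterministic function of
#'   `(seed, parameters)`.
#' @return an object of class `orientation_error` with elements `delta_R`
#'   (a [rot_series()]), `euler` (N x 3 matrix of alpha, beta, gamma in
#'   radians), `theta_max_deg` and `seed`.
#' @export
orientation_error <- function(theta_max_deg, duration, fs = 100, seed = 1L) {
  stopifnot(theta_max_deg >= 0, duration > 0, fs > 0)
  n <- round(duration * fs) + 1L
  theta <- theta_max_deg * pi / 180
  ang <- withr::with_seed(seed, {
    raw <- matrix(stats::rnorm(3L * n), nrow = n, ncol = 3L)
    raw <- apply(raw, 2L, cumsum)
    sm <- apply(raw, 2L, .moving_average_centered, width = max(1L, round(0.5 * fs)))
    if (theta == 0) {
      matrix(0, n, 3L)
    } else {
      apply(sm, 2L, function(col) col * (theta / max(abs(col))))
    }
  })
  structure(
    list(
      delta_R = rot_from_euler_zyx(ang[, 1L], ang[, 2L], ang[, 3L], fs),
      euler = ang, theta_max_deg = theta_max_deg, seed = as.integer(seed),
      fs = fs
    ),
    class = "orientation_error"
  )
}

#' @export
print.orientation_error <- function(x, ...) {
  cat(sprintf(
    "<orientation_error> theta_max = %g deg, %d samples @ %g Hz, seed %d\n",
    x$theta_max_deg, nrow(x$euler), x$fs, x$seed
  ))
  invisible(x)
}

# centred moving average, window `width` samples, truncated at the edges
.moving_average_centered <- function(x, width) {
  n <- length(x)
  half <- floor(width / 2)
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Dynamic range of a rotation error series
#'
#' The largest spectral-norm mismatch between any two rotations of the
#' series: `max over (ti, tj) of || dR(ti)' dR(tj) - I ||_2`. For a relative
#' rotation by angle `phi` this norm is `2 sin(phi / 2)`, and the trace
#' identity `tr(Ri' Rj) = <ri, rj>` (Frobenius inner product of the
#' flattened matrices) lets the full pairwise search run as one Gram-matrix
#' product. The result is invariant to a fixed rotation offset applied to
#' the whole series, and drives the error in the reconstructed acceleration
#' peak.
#'
#' @param err an `orientation_error` (see [orientation_error()]) or a
#'   [rot_series()] with at least 2 samples.
#' @return a nonnegative scalar in `[0, 2]`.
#' @export
dynamic_range <- function(err) {
  rot <- if (inherits(err, "orientation_error")) err$delta_R else err
  stopifnot(inherits(rot, "rot_series"))
  if (nrow(rot$r) < 2L) stop("need at least 2 samples", call. = FALSE)
  g_min <- min(tcrossprod(rot$r))
  sqrt(max(3 - g_min, 0))
}

#' Angular rate magnitude of a rotation error series
#'
#' Per-sample spectral norm of the finite-difference time derivative of
#' `dR(t)` (central differences inside, one-sided second-order stencils at
#' the boundaries), together with its RMS over time. For a rotation at a
#' uniform rate `r` rad/s the per-sample value equals `r`; across simulated
#' error series the RMS scales proportionally to `theta_max`. This quantity
#' drives the error in the reconstructed jerk integral.
#'
#' @param err an `orientation_error` or [rot_series()] with >= 4 samples.
#' @return a list with `series` (numeric vector, rad/s) and `rms` (scalar).
#' @export
derivative_magnitude <- function(err) {
  rot <- if (inherits(err, "orientation_error")) err$delta_R else err
  stopifnot(inherits(rot, "rot_series"))
  if (nrow(rot$r) < 4L) stop("need at least 4 samples", call. = FALSE)
  d <- .diff_matrix(rot$r, rot$fs)
  s <- .spectral_norm_3x3(d)
  list(series = s, rms = sqrt(mean(s^2)))
}

# spectral norm (largest singular value) of each row-major flattened 3x3
# matrix in an N x 9 matrix, via the closed-form symmetric eigensolver on
# M'M (Cardano / trigonometric form)
.spectral_norm_3x3 <- function(m) {
  a11 <- m[, 1L]^2 + m[, 4L]^2 + m[, 7L]^2
  a22 <- m[, 2L]^2 + m[, 5L]^2 + m[, 8L]^2
  a33 <- m[, 3L]^2 + m[, 6L]^2 + m[, 9L]^2
  a12 <- m[, 1L] * m[, 2L] + m[, 4L] * m[, 5L] + m[, 7L] * m[, 8L]
  a13 <- m[, 1L] * m[, 3L] + m[, 4L] * m[, 6L] + m[, 7L] * m[, 9L]
  a23 <- m[, 2L] * m[, 3L] + m[, 5L] * m[, 6L] + m[, 8L] * m[, 9L]
  q <- (a11 + a22 + a33) / 3
  p2 <- (a11 - q)^2 + (a22 - q)^2 + (a33 - q)^2 + 2 * (a12^2 + a13^2 + a23^2)
  p <- sqrt(p2 / 6)
  scale <- pmax(abs(q), 1)
  small <- p < 1e-14 * scale
  ps <- ifelse(small, 1, p)
  b11 <- (a11 - q) / ps; b22 <- (a22 - q) / ps; b33 <- (a33 - q) / ps
  b12 <- a12 / ps; b13 <- a13 / ps; b23 <- a23 / ps
  detb <- b11 * (b22 * b33 - b23^2) - b12 * (b12 * b33 - b23 * b13) +
    b13 * (b12 * b23 - b22 * b13)
  r <- pmin(pmax(detb / 2, -1), 1)
  lam <- q + 2 * p * cos(acos(r) / 3)
  lam[small] <- q[small]
  sqrt(pmax(lam, 0))
}
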