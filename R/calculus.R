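#' Numerical time derivative of a kinematic series
#'
#' Second-order central differences on interior samples and one-sided
#' second-order stencils at the two boundaries (no padding), so a smooth
#' signal is differentiated with `O(fs^-2)` accuracy everywhere. The `kind`
#' tag advances along the kinematic chain
#' (position -> velocity -> acceleration -> jerk, and the angular analogue).
#'
#' @param series a [kin_series()] with at least 4 samples.
#' @return a [kin_series()] of the same length and `fs`.
#' @examples
#' t <- seq(0, 1, by = 0.01)
#' v <- kin_series(cbind(t, 2 * t, 3 * t), fs = 100, kind = "velocity")
#' differentiate(v)$values[5, ]  # the constant slope (1, 2, 3)
#' @export
differentiate <- function(series) {
  stopifnot(inherits(series, "kin_series"))
  x <- series$values
  n <- nrow(x)
  if (n < 4L) stop("need at least 4 samples to differentiate", call. = FALSE)
  d <- .diff_matrix(x, series$fs)
  kin_series(d, fs = series$fs, kind = .advance_kind(series$kind))
}

# second-order finite differences, column-wise, on an N x k matrix
.diff_matrix <- function(x, fs) {
  n <- nrow(x)
  d <- matrix(0, n, ncol(x))
  d[2:(n - 1L), ] <- (x[3:n, , drop = FALSE] - x[1:(n - 2L), , drop = FALSE]) * (fs / 2)
  d[1L, ] <- (-3 * x[1L, ] + 4 * x[2L, ] - x[3L, ]) * (fs / 2)
  d[n, ] <- (3 * x[n, ] - 4 * x[n - 1L, ] + x[n - 2L, ]) * (fs / 2)
  d
}

.advance_kind <- function(kind) {
  map <- c(
    position = "velocity", velocity = "acceleration", acceleration = "jerk",
    angular_velocity = "angular_acceleration",
    angular_acceleration = "angular_jerk"
  )
  if (!kind %in% names(map)) {
    stop(sprintf("cannot differentiate a series of kind '%s'", kind), call. = FALSE)
  }
  unname(map[kind])
}

#' Cumulative trapezoidal integral of a kinematic series
#'
#' @param series a [kin_series()].
#' @param initial 3-vector value of the integral at the first sample.
#' @return a [kin_series()] with the `kind` tag lowered
#'   (e.g. acceleration -> velocity).
#' @examples
#' a <- kin_series(matrix(rep(c(1, 0, 0), each = 101), ncol = 3),
#'                 fs = 100, kind = "acceleration")
#' v <- integrate_cumulative(a, c(0, 0, 0))
#' v$values[101, ]  # (1, 0, 0): integral of a unit constant over 1 s
#' @export
integrate_cumulative <- function(series, initial = c(0, 0, 0)) {
  stopifnot(inherits(series, "kin_series"), length(initial) == 3L)
  x <- series$values
  n <- nrow(x)
  steps <- (x[2:n, , drop = FALSE] + x[1:(n - 1L), , drop = FALSE]) / (2 * series$fs)
  out <- rbind(0, apply(steps, 2L, cumsum))
  out <- sweep(out, 2L, as.double(initial), `+`)
  kin_series(out, fs = series$fs, kind = .lower_kind(series$kind))
}

.lower_kind <- function(kind) {
  map <- c(
    velocity = "position", acceleration = "velocity", jerk = "acceleration",
    angular_acceleration = "angular_velocity",
    angular_jerk = "angular_acceleration"
  )
  if (!kind %in% names(map)) {
    stop(sprintf("cannot integrate a series of kind '%s'", kind), call. = FALSE)
  }
  unname(map[kind])
}

#' Per-sample Euclidean norm of a series
#'
#' The speed profile `||v(t)||_2` when applied to a velocity series.
#'
#' @param series a [kin_series()].
#' @return a nonnegative numeric vector of length `N`.
#' @export
norm_series <- function(series) {
  stopifnot(inherits(series, "kin_series"))
  sqrt(rowSums(series$values^2))
}

#' Rotate a kinematic series sample-by-sample
#'
#' Applies `R(t) v(t)` per sample. Rotations are orthonormal, so the
#' per-sample norm (and with it the speed profile) is preserved.
#'
#' @param series a [kin_series()].
#' @param rot a [rot_series()] with the same `N` and `fs`.
#' @return a rotated [kin_series()] of the same kind.
#' @export
apply_rotation <- function(series, rot) {
  stopifnot(inherits(series, "kin_series"), inherits(rot, "rot_series"))
  if (nrow(series$values) != nrow(rot$r) || series$fs != rot$fs) {
    stop("series and rotation series must share N and fs", call. = FALSE)
  }
  kin_series(.rot_apply_mat(rot, series$values), fs = series$fs, kind = series$kind)
}

#' Zero-phase second-order Butterworth low-pass filter
#'
#' Forward-backward application of a second-order Butterworth design
#' (effective order 4, zero lag, DC gain exactly 1). Edges are handled with
#' odd reflection padding and steady-state initial filter conditions, so a
#' constant signal passes through unchanged.
#'
#' @param series a [kin_series()].
#' @param fc cut-off frequency in Hz, `0 < fc < fs / 2`.
#' @return a filtered [kin_series()] of the same kind, length and `fs`.
#' @export
lowpass_zero_phase <- function(series, fc) {
  stopifnot(inherits(series, "kin_series"))
  fs <- series$fs
  if (!is.numeric(fc) || length(fc) != 1L || fc <= 0 || fc >= fs / 2) {
    stop("`fc` must satisfy 0 < fc < fs/2", call. = FALSE)
  }
  bf <- signal::butter(2, fc / (fs / 2), type = "low")
  out <- apply(series$values, 2L, .filtfilt_padded, b = bf$b, a = bf$a)
  kin_series(out, fs = fs, kind = series$kind)
}

# forward-backward IIR filtering with odd-reflection padding and
# steady-state initial conditions (so constants are exactly invariant)
.filtfilt_padded <- function(x, b, a) {
  nfilt <- max(length(a), length(b))
  pad <- 3L * nfilt
  n <- length(x)
  if (n <= pad) pad <- n - 1L
  head_pad <- 2 * x[1L] - x[(pad + 1L):2L]
  tail_pad <- 2 * x[n] - x[(n - 1L):(n - pad)]
  xp <- c(head_pad, x, tail_pad)
  zi <- .lfilter_zi(b, a)
  y <- .iir_filter(b, a, xp, zi * xp[1L])
  y <- rev(.iir_filter(b, a, rev(y), zi * y[length(y)]))
  y[(pad + 1L):(pad + n)]
}

# steady-state state vector of the direct-form-II-transposed filter for a
# unit step input
.lfilter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  b <- c(b, numeric(n - length(b)))
  a <- c(a, numeric(n - length(a)))
  b <- b / a[1L]; a <- a / a[1L]
  m <- n - 1L
  A <- diag(1, m) - cbind(-a[2:n], rbind(diag(1, m - 1L), 0))
  rhs <- b[2:n] - a[2:n] * b[1L]
  solve(A, rhs)
}

.iir_filter <- function(b, a, x, zi) {
  n <- max(length(a), length(b))
  b <- c(b, numeric(n - length(b)))
  a <- c(a, numeric(n - length(a)))
  b <- b / a[1L]; a <- a / a[1L]
  y <- numeric(length(x))
  z <- c(zi, 0)
  for (i in seq_along(x)) {
    y[i] <- b[1L] * x[i] + z[1L]
    for (k in seq_len(n - 1L)) {
      z[k] <- b[k + 1L] * x[i] + z[k + 1L] - a[k + 1L] * y[i]
    }
  }
  y
}

# trapezoidal integral of a sampled scalar signal
.trapz <- function(y, fs) {
  n <- length(y)
  (sum(y) - (y[1L] + y[n]) / 2) / fs
}
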