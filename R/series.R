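#' Uniformly sampled 3-vector kinematic time series
#'
#' The basic container used throughout the package: an `N x 3` matrix of
#' samples (one row per time step, columns x/y/z in a fixed reference frame),
#' a sampling frequency `fs` in Hz, and a `kind` tag recording which kinematic
#' variable the series holds. SI units are implied by the tag: m (position),
#' m/s (velocity), m/s^2 (acceleration), m/s^3 (jerk) and rad/s
#' (angular velocity).
#'
#' @param values numeric `N x 3` matrix (or a data frame with columns
#'   `x`, `y`, `z`); `N >= 4` so that second differences are defined.
#' @param fs sampling frequency in Hz (> 0).
#' @param kind one of `"position"`, `"velocity"`, `"acceleration"`, `"jerk"`,
#'   `"angular_velocity"`, `"angular_acceleration"`, `"angular_jerk"`.
#'
#' @return an object of class `kin_series`.
#' @examples
#' t <- seq(0, 1, by = 0.01)
#' v <- kin_series(cbind(sin(pi * t), 0, 0), fs = 100, kind = "velocity")
#' v
#' @export
kin_series <- function(values, fs, kind) {
  if (is.data.frame(values)) {
    stopifnot(all(c("x", "y", "z") %in% names(values)))
    values <- as.matrix(values[, c("x", "y", "z")])
  }
  values <- unname(as.matrix(values))
  storage.mode(values) <- "double"
  if (ncol(values) != 3L) {
    stop("`values` must have exactly 3 columns (x, y, z)", call. = FALSE)
  }
  if (nrow(values) < 4L) {
    stop("a kin_series needs at least 4 samples", call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop("all values must be finite", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("`fs` must be a single positive number (Hz)", call. = FALSE)
  }
  kind <- match.arg(kind, .kin_kinds)
  structure(
    list(values = values, fs = as.double(fs), kind = kind),
    class = "kin_series"
  )
}

.kin_kinds <- c(
  "position", "velocity", "acceleration", "jerk",
  "angular_velocity", "angular_acceleration", "angular_jerk"
)

#' @export
print.kin_series <- function(x, ...) {
  cat(sprintf(
    "<kin_series> %s: %d samples @ %g Hz (%.3f s)\n",
    x$kind, nrow(x$values), x$fs, duration(x)
  ))
  invisible(x)
}

#' Number of samples in a series
#' @param x a `kin_series` or `rot_series`.
#' @return integer sample count.
#' @export
n_samples <- function(x) {
  if (inherits(x, "rot_series")) nrow(x$r) else nrow(x$values)
}

#' Duration spanned by a series
#' @param x a `kin_series` or `rot_series`.
#' @return duration `(N - 1) / fs` in seconds.
#' @export
duration <- function(x) (n_samples(x) - 1L) / x$fs

#' Sample times of a series
#' @param x a `kin_series` or `rot_series`.
#' @return numeric vector of times in seconds, starting at 0.
#' @export
time_points <- function(x) seq(0L, n_samples(x) - 1L) / x$fs

#' @importFrom tibble as_tibble
#' @export
as_tibble.kin_series <- function(x, ...) {
  vals <- x$values
  tibble::tibble(
    t = time_points(x),
    x = vals[, 1L], y = vals[, 2L], z = vals[, 3L]
  )
}

#' Time series of proper rotation matrices
#'
#' Stores `N` rotation matrices sampled on the same clock as a paired
#' [kin_series()]. Internally the matrices live in an `N x 9` matrix, one
#' row-major flattened 3x3 matrix per row, which keeps per-sample algebra
#' vectorised.
#'
#' @param rotations a `3 x 3 x N` array, an `N x 9` row-major matrix, or a
#'   single 3x3 matrix together with `n`.
#' @param fs sampling frequency in Hz.
#' @param n number of samples when replicating a single matrix.
#' @param tol orthonormality tolerance: each matrix must satisfy
#'   `max|R'R - I| <= tol` and `|det(R) - 1| <= tol`.
#' @return an object of class `rot_series`.
#' @examples
#' rot_series(diag(3), fs = 100, n = 10)
#' @export
rot_series <- function(rotations, fs, n = NULL, tol = 1e-9) {
  if (is.array(rotations) && length(dim(rotations)) == 3L) {
    stopifnot(dim(rotations)[1:2] == c(3L, 3L))
    nr <- dim(rotations)[3L]
    r <- t(apply(rotations, 3L, function(m) as.vector(t(m))))
    dim(r) <- c(nr, 9L)
  } else if (is.matrix(rotations) && all(dim(rotations) == c(3L, 3L))) {
    if (is.null(n)) stop("supply `n` when replicating a single rotation", call. = FALSE)
    r <- matrix(as.vector(t(rotations)), nrow = n, ncol = 9L, byrow = TRUE)
  } else if (is.matrix(rotations) && ncol(rotations) == 9L) {
    r <- unname(rotations)
  } else {
    stop("`rotations` must be 3x3x N array, N x 9 matrix, or one 3x3 matrix", call. = FALSE)
  }
  storage.mode(r) <- "double"
  if (!all(is.finite(r))) stop("rotations must be finite", call. = FALSE)
  out <- structure(list(r = r, fs = as.double(fs)), class = "rot_series")
  .check_rotations(out, tol)
  out
}

.check_rotations <- function(rs, tol) {
  r <- rs$r
  # R'R = I, columns of R = (r11,r12,r13,r21,...,r33) row-major
  c1 <- cbind(r[, 1L], r[, 4L], r[, 7L])
  c2 <- cbind(r[, 2L], r[, 5L], r[, 8L])
  c3 <- cbind(r[, 3L], r[, 6L], r[, 9L])
  err <- pmax(
    abs(rowSums(c1 * c1) - 1), abs(rowSums(c2 * c2) - 1),
    abs(rowSums(c3 * c3) - 1), abs(rowSums(c1 * c2)),
    abs(rowSums(c1 * c3)), abs(rowSums(c2 * c3))
  )
  dets <- rowSums(c1 * .cross_rows(c2, c3))
  if (max(err) > tol || max(abs(dets - 1)) > tol) {
    stop(sprintf(
      "rotation matrices are not orthonormal within tol = %g (max deviation %g)",
      tol, max(err, abs(dets - 1))
    ), call. = FALSE)
  }
  invisible(rs)
}

.cross_rows <- function(a, b) {
  cbind(
    a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
    a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
    a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L]
  )
}

#' @export
print.rot_series <- function(x, ...) {
  cat(sprintf(
    "<rot_series> %d rotation matrices @ %g Hz\n", nrow(x$r), x$fs
  ))
  invisible(x)
}

#' Identity rotation series
#' @param n number of samples.
#' @param fs sampling frequency in Hz.
#' @return a `rot_series` of `n` identity matrices.
#' @export
rot_identity <- function(n, fs) rot_series(diag(3), fs = fs, n = n)

#' Transpose (invert) every rotation in a series
#' @param rot a `rot_series`.
#' @return the `rot_series` of per-sample inverses.
#' @export
rot_transpose <- function(rot) {
  structure(
    list(r = rot$r[, c(1L, 4L, 7L, 2L, 5L, 8L, 3L, 6L, 9L), drop = FALSE], fs = rot$fs),
    class = "rot_series"
  )
}

#' Per-sample composition of two rotation series
#'
#' Returns the series whose sample `i` is `A[i] %*% B[i]`.
#'
#' @param a,b `rot_series` objects with matching length and `fs`.
#' @return a `rot_series`.
#' @export
rot_compose <- function(a, b) {
  if (nrow(a$r) != nrow(b$r) || a$fs != b$fs) {
    stop("rotation series must share N and fs", call. = FALSE)
  }
  ra <- a$r; rb <- b$r
  out <- matrix(0, nrow(ra), 9L)
  for (i in 1:3) for (j in 1:3) {
    k <- (i - 1L) * 3L + j
    out[, k] <- ra[, (i - 1L) * 3L + 1L] * rb[, j] +
      ra[, (i - 1L) * 3L + 2L] * rb[, 3L + j] +
      ra[, (i - 1L) * 3L + 3L] * rb[, 6L + j]
  }
  structure(list(r = out, fs = a$fs), class = "rot_series")
}

# per-sample matrix-vector product R v on an N x 3 matrix of vectors
.rot_apply_mat <- function(rot, v) {
  r <- rot$r
  cbind(
    r[, 1L] * v[, 1L] + r[, 2L] * v[, 2L] + r[, 3L] * v[, 3L],
    r[, 4L] * v[, 1L] + r[, 5L] * v[, 2L] + r[, 6L] * v[, 3L],
    r[, 7L] * v[, 1L] + r[, 8L] * v[, 2L] + r[, 9L] * v[, 3L]
  )
}

#' Rotation series from z-y-x Euler angle sequences
#'
#' Builds `R(t) = Rz(alpha) Ry(beta) Rx(gamma)` per sample, the
#' parameterisation used for orientation reconstruction errors.
#'
#' @param alpha,beta,gamma numeric vectors of angles in radians (about the
#'   z, y and x axes respectively), equal length.
#' @param fs sampling frequency in Hz.
#' @return a `rot_series`.
#' @export
rot_from_euler_zyx <- function(alpha, beta, gamma, fs) {
  stopifnot(length(alpha) == length(beta), length(beta) == length(gamma))
  ca <- cos(alpha); sa <- sin(alpha)
  cb <- cos(beta);  sb <- sin(beta)
  cg <- cos(gamma); sg <- sin(gamma)
  r <- cbind(
    ca * cb, ca * sb * sg - sa * cg, ca * sb * cg + sa * sg,
    sa * cb, sa * sb * sg + ca * cg, sa * sb * cg - ca * sg,
    -sb,     cb * sg,                cb * cg
  )
  structure(list(r = r, fs = as.double(fs)), class = "rot_series")
}

#' Rotation series from unit quaternions
#'
#' Quaternions are scalar-first `(w, x, y, z)`, Hamilton convention, and are
#' normalised before conversion.
#'
#' @param q numeric `N x 4` matrix of quaternions.
#' @param fs sampling frequency in Hz.
#' @return a `rot_series`.
#' @export
rot_from_quat <- function(q, fs) {
  q <- as.matrix(q)
  stopifnot(ncol(q) == 4L)
  q <- q / sqrt(rowSums(q^2))
  w <- q[, 1L]; x <- q[, 2L]; y <- q[, 3L]; z <- q[, 4L]
  r <- cbind(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  )
  structure(list(r = r, fs = as.double(fs)), class = "rot_series")
}

#' @export
as.array.rot_series <- function(x, ...) {
  n <- nrow(x$r)
  out <- array(0, c(3L, 3L, n))
  for (i in seq_len(n)) out[, , i] <- matrix(x$r[i, ], 3L, 3L, byrow = TRUE)
  out
}

#' Gravity vector
#'
#' Earth-frame gravity used by the IMU measurement model. The package
#' convention is `g = (0, 0, +9.81)` m/s^2: a static accelerometer whose axes
#' are aligned with the earth frame reads `+9.81` on its z axis.
#'
#' @param g a 3-vector in m/s^2.
#' @param allow_nonstandard set `TRUE` to permit a magnitude other than
#'   9.81 m/s^2 (e.g. zero gravity for tests).
#' @return a numeric 3-vector of class `gravity_vector`.
#' @export
gravity_vector <- function(g = c(0, 0, 9.81), allow_nonstandard = FALSE) {
  g <- as.double(g)
  stopifnot(length(g) == 3L, all(is.finite(g)))
  if (!allow_nonstandard && abs(sqrt(sum(g^2)) - 9.81) > 1e-6) {
    stop("|g| must be 9.81 m/s^2 unless `allow_nonstandard = TRUE`", call. = FALSE)
  }
  structure(g, class = "gravity_vector")
}
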