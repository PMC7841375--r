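#' Read and write kinematic series as delimited text
#'
#' The on-disk schema is a headered CSV with columns `t, x, y, z`; time must
#' be uniformly sampled (the sampling rate is inferred from the median time
#' step and checked for uniformity).
#'
#' @param path file path.
#' @param kind kinematic kind tag for the series read (see [kin_series()]).
#' @return `read_kin_csv()` returns a [kin_series()]; `write_kin_csv()`
#'   returns `path` invisibly.
#' @export
read_kin_csv <- function(path, kind = "velocity") {
  df <- readr::read_csv(path, show_col_types = FALSE)
  stopifnot(all(c("t", "x", "y", "z") %in% names(df)))
  fs <- .infer_fs(df$t)
  kin_series(as.matrix(df[, c("x", "y", "z")]), fs = fs, kind = kind)
}

#' @rdname read_kin_csv
#' @param series a [kin_series()] to write.
#' @export
write_kin_csv <- function(series, path) {
  readr::write_csv(as_tibble(series), path)
  invisible(path)
}

.infer_fs <- function(t) {
  dt <- diff(t)
  if (length(dt) < 1L || any(dt <= 0)) {
    stop("time column must be strictly increasing", call. = FALSE)
  }
  step <- stats::median(dt)
  if (max(abs(dt - step)) > 1e-6 * step + 1e-12) {
    stop("time column is not uniformly sampled", call. = FALSE)
  }
  1 / step
}

#' Read a raw IMU stream from delimited text
#'
#' Schema: headered CSV with columns `t, ax, ay, az, gx, gy, gz` and either
#' quaternion columns `qw, qx, qy, qz` (scalar-first, Hamilton convention,
#' sensor-to-earth) or no orientation. Alternatively a separate
#' rotation-matrix file (9 columns `r11..r33`, row-major, one row per
#' sample) can supply the orientation estimate.
#'
#' @param path CSV file path.
#' @param rotation_path optional path to a 9-column rotation-matrix CSV.
#' @return an [imu_reading()].
#' @export
read_imu_csv <- function(path, rotation_path = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("t", "ax", "ay", "az", "gx", "gy", "gz")
  stopifnot(all(need %in% names(df)))
  fs <- .infer_fs(df$t)
  accel <- kin_series(as.matrix(df[, c("ax", "ay", "az")]), fs, "acceleration")
  gyro <- kin_series(as.matrix(df[, c("gx", "gy", "gz")]), fs, "angular_velocity")
  est <- NULL
  if (!is.null(rotation_path)) {
    rm9 <- as.matrix(readr::read_csv(rotation_path, show_col_types = FALSE))
    stopifnot(ncol(rm9) == 9L)
    est <- rot_series(unname(rm9), fs = fs, tol = 1e-6)
  } else if (all(c("qw", "qx", "qy", "qz") %in% names(df))) {
    est <- rot_from_quat(as.matrix(df[, c("qw", "qx", "qy", "qz")]), fs)
  }
  imu_reading(accel, gyro, orientation_estimate = est)
}
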