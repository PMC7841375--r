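#' @importFrom rlang %||%
NULL

#' Configuration for the factorial validation grid
#'
#' Defaults reproduce the full study design: base 1 s, 15 cm minimum-jerk
#' movements with {1, 2, 5, 10} via-points (25 seeded repetitions each),
#' time-scaled to durations {2.5, 5, 10, 20} s, crossed with orientation
#' error magnitudes {5, 25, 50} degrees (5 seeded realisations each) —
#' 4 x 25 x 4 x 3 x 5 = 6,000 condition records.
#'
#' @param n_via via-point counts.
#' @param durations movement durations in seconds.
#' @param theta_max_deg orientation error magnitudes in degrees.
#' @param n_movements seeded movement repetitions per via-point count.
#' @param n_error_reps seeded error realisations per condition.
#' @param fs simulation sampling frequency in Hz.
#' @param amplitude_m total path length in metres.
#' @param base_duration_s duration of the base movement before time scaling.
#' @return a list of class `grid_config`.
#' @export
grid_config <- function(n_via = c(1L, 2L, 5L, 10L),
                        durations = c(2.5, 5, 10, 20),
                        theta_max_deg = c(5, 25, 50),
                        n_movements = 25L,
                        n_error_reps = 5L,
                        fs = 100,
                        amplitude_m = 0.15,
                        base_duration_s = 1) {
  structure(
    list(
      n_via = as.integer(n_via), durations = durations,
      theta_max_deg = theta_max_deg, n_movements = as.integer(n_movements),
      n_error_reps = as.integer(n_error_reps), fs = fs,
      amplitude_m = amplitude_m, base_duration_s = base_duration_s
    ),
    class = "grid_config"
  )
}

#' @export
print.grid_config <- function(x, ...) {
  n <- length(x$n_via) * x$n_movements * length(x$durations) *
    length(x$theta_max_deg) * x$n_error_reps
  cat(sprintf(
    "<grid_config> %d x %d x %d x %d x %d = %d records @ fs = %g Hz\n",
    length(x$n_via), x$n_movements, length(x$durations),
    length(x$theta_max_deg), x$n_error_reps, n, x$fs
  ))
  invisible(x)
}

# deterministic per-condition seed fan-out: a rolling polynomial hash of the
# condition label, folded into [0, 2^31 - 2]; independent of execution order
.seed_from <- function(master, ...) {
  label <- paste(vapply(list(...), format, character(1L)), collapse = "|")
  h <- as.double(master %% 2147483647L)
  for (code in utf8ToInt(label)) h <- (h * 31 + code) %% 2147483647
  as.integer(h)
}

#' Run the factorial simulation grid
#'
#' For every condition (via-point count, movement repetition, duration,
#' error magnitude, error realisation): simulate the base movement,
#' time-scale it, generate the orientation error series, form the
#' reconstructed linear acceleration `dR x'' + (dR - I) g` and angular
#' velocity `dR omega` through the IMU forward/reconstruction model, compute
#' SPARC, LDLJ-V and LDLJ-A on the true and reconstructed signals, and
#' summarise the error series. The simulated linear velocity doubles as the
#' angular velocity for the rotational analysis. Everything is reproducible
#' bit-for-bit from the master seed: each condition draws its own seed from a
#' deterministic hash of the condition tuple, independent of execution order.
#'
#' @param config a [grid_config()].
#' @param seed master integer seed.
#' @param g a [gravity_vector()].
#' @param progress print a line per via-point/movement block.
#' @return a tibble with one row per condition record:
#'   identifiers (`n_via`, `movement_seed_idx`, `duration_s`,
#'   `theta_max_deg`, `error_seed_idx`, `movement_seed`, `error_seed`), true
#'   and reconstructed smoothness (`sal_true`, `sal_recon`, `ldljv_true`,
#'   `ldljv_recon`, `ldlja_true`, `ldlja_recon`), `sgr`, percentage errors
#'   (`jerk_error_pct`, `accl_peak_error_pct`), relative smoothness errors
#'   (`rel_error_sparc`, `rel_error_ldljv`, `rel_error_ldlja`) and error
#'   series summaries (`delta_range`, `delta_deriv_rms`). Conditions that
#'   fail are dropped with a warning identifying the condition tuple.
#' @examples
#' cfg <- grid_config(n_via = c(1, 5), durations = 2.5, theta_max_deg = 25,
#'                    n_movements = 2, n_error_reps = 1)
#' run_grid(cfg, seed = 1)
#' @export
run_grid <- function(config = grid_config(), seed = 1L, g = gravity_vector(),
                     progress = FALSE) {
  stopifnot(inherits(config, "grid_config"))
  n_total <- length(config$n_via) * config$n_movements *
    length(config$durations) * length(config$theta_max_deg) *
    config$n_error_reps
  cols <- c(
    "n_via", "movement_seed_idx", "duration_s", "theta_max_deg",
    "error_seed_idx", "movement_seed", "error_seed",
    "sal_true", "sal_recon", "ldljv_true", "ldljv_recon",
    "ldlja_true", "ldlja_recon", "sgr",
    "jerk_error_pct", "accl_peak_error_pct",
    "rel_error_sparc", "rel_error_ldljv", "rel_error_ldlja",
    "delta_range", "delta_deriv_rms"
  )
  rec <- matrix(NA_real_, n_total, length(cols), dimnames = list(NULL, cols))
  failed <- character(0)
  row <- 0L
  for (nv in config$n_via) {
    for (mi in seq_len(config$n_movements)) {
      mseed <- .seed_from(seed, "movement", nv, mi)
      base <- via_point_movement(nv, fs = config$fs, seed = mseed,
                                 amplitude = config$amplitude_m,
                                 duration = config$base_duration_s)
      if (progress) {
        message(sprintf("n_via = %d, movement %d/%d", nv, mi, config$n_movements))
      }
      for (dur in config$durations) {
        mov <- time_scale(base, dur)
        omega <- kin_series(mov$velocity$values, fs = config$fs,
                            kind = "angular_velocity")
        reading0 <- forward_measure(mov, rot_identity(n_samples(omega), config$fs),
                                    g = g, omega = omega)
        truth <- list(
          sal = sparc(omega)$sal,
          ldljv = ldlj_v(omega)$value,
          ldlja_fit = ldlj_a(mov$acceleration),
          sgr = sgr(reading0$accel, g)
        )
        for (th in config$theta_max_deg) {
          for (ei in seq_len(config$n_error_reps)) {
            row <- row + 1L
            eseed <- .seed_from(seed, "error", nv, mi, dur, th, ei)
            res <- tryCatch(
              .grid_record(mov, omega, reading0, truth, th, ei, eseed, g, config),
              error = function(e) e
            )
            if (inherits(res, "error")) {
              failed <- c(failed, sprintf(
                "n_via=%d movement=%d T=%g theta=%g rep=%d: %s",
                nv, mi, dur, th, ei, conditionMessage(res)
              ))
              row <- row - 1L
              next
            }
            rec[row, ] <- c(nv, mi, dur, th, ei, mseed, eseed, res)
          }
        }
      }
    }
  }
  if (length(failed) > 0) {
    warning(sprintf(
      "%d condition(s) failed and were dropped:\n%s",
      length(failed), paste(failed, collapse = "\n")
    ), call. = FALSE)
  }
  out <- tibble::as_tibble(as.data.frame(rec[seq_len(row), , drop = FALSE]))
  out$n_via <- as.integer(out$n_via)
  out$movement_seed_idx <- as.integer(out$movement_seed_idx)
  out$error_seed_idx <- as.integer(out$error_seed_idx)
  out
}

# one (movement, error realisation) record; returns the numeric columns
# after the identifier block
.grid_record <- function(mov, omega, reading0, truth, th, ei, eseed, g, config) {
  err <- orientation_error(th, duration = mov$duration_s, fs = config$fs,
                           seed = eseed)
  reading <- imu_reading(reading0$accel, reading0$gyro,
                         orientation_estimate = err$delta_R)
  lin <- reconstruct_linear(reading, g = g, truth = mov)
  ang <- reconstruct_angular(reading, truth_omega = omega)
  sal_recon <- sparc(ang$omega_earth)$sal
  ldljv_recon <- ldlj_v(ang$omega_earth)$value
  ldlja_recon_fit <- ldlj_a(lin$accel_earth)
  errs <- jerk_and_peak_errors(lin$accel_earth, mov$acceleration)
  dm <- derivative_magnitude(err)
  c(
    sal_true = truth$sal, sal_recon = sal_recon,
    ldljv_true = truth$ldljv, ldljv_recon = ldljv_recon,
    ldlja_true = truth$ldlja_fit$value, ldlja_recon = ldlja_recon_fit$value,
    sgr = truth$sgr,
    jerk_error_pct = errs$jerk_error_pct,
    accl_peak_error_pct = errs$accl_peak_error_pct,
    rel_error_sparc = relative_error(sal_recon, truth$sal),
    rel_error_ldljv = relative_error(ldljv_recon, truth$ldljv),
    rel_error_ldlja = relative_error(ldlja_recon_fit$value, truth$ldlja_fit$value),
    delta_range = dynamic_range(err),
    delta_deriv_rms = dm$rms
  )
}
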