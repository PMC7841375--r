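#' Spectral arc length (SPARC) movement smoothness
#'
#' SPARC quantifies movement smoothness as the negative arc length of the
#' normalised Fourier magnitude spectrum of the speed profile, evaluated up to
#' an adaptive cut-off frequency. More negative values indicate less smooth
#' (more intermittent) movement. Because the measure is computed on the
#' per-sample norm of the velocity, it is exactly invariant to amplitude
#' scaling and to any rotation of the reference frame; in particular it can be
#' applied directly to raw gyroscope angular velocity without knowing the
#' sensor's orientation.
#'
#' The adaptive cut-off works on a magnitude spectrum zero-padded to
#' `2^(ceiling(log2(N)) + pad_level)` points and normalised by its DC value:
#' the cut-off is the largest frequency not exceeding `fc_max` at which the
#' normalised magnitude still reaches `amp_threshold`, taking the band
#' growing contiguously from 0.
#'
#' @param velocity a [kin_series()] of kind `velocity` or `angular_velocity`.
#' @param pad_level zero-padding exponent added on top of the next power of
#'   two (default 4).
#' @param fc_max maximum admissible cut-off frequency in Hz (default 20 Hz,
#'   i.e. 40*pi rad/s). Use 6 Hz to mirror common motion-capture
#'   preprocessing of clinical upper-limb data.
#' @param amp_threshold normalised amplitude threshold for the adaptive
#'   cut-off (default 0.05).
#' @return an object of class `sparc_result` with elements `sal` (the
#'   smoothness value, dimensionless, negative), `omega_c` (adopted cut-off,
#'   rad/s) and `spectrum` (tibble of the normalised magnitude spectrum up to
#'   `fc_max`).
#' @examples
#' mov <- min_jerk_segment(0.15, 1, fs = 100)
#' sparc(mov$velocity)
#' @export
sparc <- function(velocity, pad_level = 4, fc_max = 20, amp_threshold = 0.05) {
  stopifnot(inherits(velocity, "kin_series"))
  if (!velocity$kind %in% c("velocity", "angular_velocity")) {
    stop("SPARC is defined on velocity (linear or angular) only", call. = FALSE)
  }
  fs <- velocity$fs
  if (fc_max >= fs / 2) {
    stop("`fc_max` must be below the Nyquist frequency fs/2", call. = FALSE)
  }
  speed <- norm_series(velocity)
  n <- length(speed)
  nfft <- 2^(ceiling(log2(n)) + pad_level)
  mag <- Mod(stats::fft(c(speed, numeric(nfft - n))))[1:(nfft / 2 + 1L)]
  if (mag[1L] == 0) {
    stop("speed profile is identically zero: V(0) = 0, spectrum undefined", call. = FALSE)
  }
  freq <- (0:(nfft / 2)) * fs / nfft
  vhat <- mag / mag[1L]
  sel <- freq <= fc_max
  f_sel <- freq[sel]
  v_sel <- vhat[sel]
  above <- which(v_sel >= amp_threshold)
  band <- seq_len(max(above))
  f_band <- f_sel[band]
  v_band <- v_sel[band]
  fc <- f_band[length(f_band)]
  sal <- -sum(sqrt((diff(f_band) / (fc - f_band[1L]))^2 + diff(v_band)^2))
  structure(
    list(
      sal = sal,
      omega_c = 2 * pi * fc,
      spectrum = tibble::tibble(freq_hz = f_sel, magnitude = v_sel),
      params = list(pad_level = pad_level, fc_max = fc_max,
                    amp_threshold = amp_threshold, fs = fs)
    ),
    class = "sparc_result"
  )
}

#' @export
print.sparc_result <- function(x, ...) {
  cat(sprintf(
    "<sparc_result> SAL = %.4f (cut-off %.2f rad/s = %.2f Hz)\n",
    x$sal, x$omega_c, x$omega_c / (2 * pi)
  ))
  invisible(x)
}

#' Log dimensionless jerk from velocity (LDLJ-V)
#'
#' `LDLJ-V = -ln( (t2 - t1)^3 / v_peak^2 * integral ||d^2 v / dt^2||^2 dt )`.
#' Jerk is obtained by double numerical differentiation of the velocity and
#' integrated by the trapezoid rule; `v_peak` is the maximum of the speed
#' profile (first sample attaining the maximum on ties). The measure is
#' exactly amplitude-invariant and duration-invariant up to discretisation
#' error, and applies equally to angular velocity.
#'
#' @param velocity a [kin_series()] of kind `velocity` or `angular_velocity`.
#' @param prefilter_fc optional low-pass cut-off in Hz applied with
#'   [lowpass_zero_phase()] before differentiation (off by default; 6 Hz is a
#'   common choice for measured clinical data).
#' @return an object of class `ldlj_result` with elements `value`,
#'   `jerk_integral`, `peak`, `duration` and `measure`.
#' @examples
#' mov <- min_jerk_segment(0.15, 1, fs = 100)
#' ldlj_v(mov$velocity)  # -ln(204.8) for a single minimum-jerk stroke
#' @export
ldlj_v <- function(velocity, prefilter_fc = NULL) {
  stopifnot(inherits(velocity, "kin_series"))
  if (!velocity$kind %in% c("velocity", "angular_velocity")) {
    stop("LDLJ-V is defined on velocity (linear or angular) only", call. = FALSE)
  }
  if (!is.null(prefilter_fc)) velocity <- lowpass_zero_phase(velocity, prefilter_fc)
  v_peak <- max(norm_series(velocity))
  if (v_peak <= 0) stop("degenerate movement: peak speed is zero", call. = FALSE)
  jerk <- differentiate(differentiate(velocity))
  ij <- .trapz(norm_series(jerk)^2, velocity$fs)
  dur <- duration(velocity)
  dlj <- dur^3 / v_peak^2 * ij
  structure(
    list(value = -log(dlj), jerk_integral = ij, peak = v_peak,
         duration = dur, measure = "ldlj_v"),
    class = "ldlj_result"
  )
}

#' Log dimensionless jerk from acceleration (LDLJ-A)
#'
#' A variant of the log dimensionless jerk that works directly on
#' (reconstructed) acceleration, avoiding the drift-prone integration to
#' velocity that IMU data would otherwise require:
#' `LDLJ-A = -ln( (t2 - t1) / a_peak^2 * integral ||da/dt||^2 dt )`,
#' where `a_peak` is the peak norm of the *mean-subtracted* acceleration.
#' For an ideal discrete movement the temporal mean of acceleration is zero
#' and the subtraction changes nothing; for reconstructed signals it removes
#' the constant part of imperfect gravity removal. The mean affects only
#' `a_peak`, never the jerk integral (the jerk of a constant is zero).
#'
#' @param acceleration a [kin_series()] of kind `acceleration`.
#' @param prefilter_fc optional low-pass cut-off in Hz (off by default).
#' @return an object of class `ldlj_result`.
#' @examples
#' mov <- min_jerk_segment(0.15, 1, fs = 100)
#' ldlj_a(mov$acceleration)  # -ln(21.6) for a single minimum-jerk stroke
#' @export
ldlj_a <- function(acceleration, prefilter_fc = NULL) {
  stopifnot(inherits(acceleration, "kin_series"))
  if (acceleration$kind != "acceleration") {
    stop("LDLJ-A is defined on acceleration only", call. = FALSE)
  }
  if (!is.null(prefilter_fc)) {
    acceleration <- lowpass_zero_phase(acceleration, prefilter_fc)
  }
  fs <- acceleration$fs
  dur <- duration(acceleration)
  # temporal mean by the trapezoid rule, per axis
  abar <- apply(acceleration$values, 2L, function(col) .trapz(col, fs)) / dur
  centred <- sweep(acceleration$values, 2L, abar)
  a_peak <- max(sqrt(rowSums(centred^2)))
  jerk <- differentiate(acceleration)
  ij <- .trapz(norm_series(jerk)^2, fs)
  if (a_peak <= 0 || ij <= 0) {
    stop("degenerate movement: constant acceleration has no jerk content", call. = FALSE)
  }
  dlj <- dur / a_peak^2 * ij
  structure(
    list(value = -log(dlj), jerk_integral = ij, peak = a_peak,
         duration = dur, measure = "ldlj_a"),
    class = "ldlj_result"
  )
}

#' @export
print.ldlj_result <- function(x, ...) {
  cat(sprintf(
    "<ldlj_result> %s = %.4f (jerk integral %.4g, peak %.4g, duration %.3g s)\n",
    toupper(gsub("_", "-", x$measure)), x$value, x$jerk_integral, x$peak, x$duration
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname sparc
#' @param x a `sparc_result`.
#' @param ... unused.
#' @export
tidy.sparc_result <- function(x, ...) x$spectrum

#' @rdname sparc
#' @export
glance.sparc_result <- function(x, ...) {
  tibble::tibble(
    measure = "sparc", sal = x$sal, omega_c = x$omega_c,
    fc_hz = x$omega_c / (2 * pi)
  )
}

#' @rdname ldlj_v
#' @param x an `ldlj_result`.
#' @param ... unused.
#' @export
tidy.ldlj_result <- function(x, ...) {
  tibble::tibble(
    measure = x$measure, value = x$value, jerk_integral = x$jerk_integral,
    peak = x$peak, duration = x$duration
  )
}

#' @rdname ldlj_v
#' @export
glance.ldlj_result <- function(x, ...) tidy(x)
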