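# independent SPARC oracle: direct DFT of the speed profile (no stats::fft,
# no shared padding logic), normalised spectrum, adaptive band from 0, chord
# arc length
sparc_oracle <- function(velocity, pad_level = 4, fc_max = 20,
                         amp_threshold = 0.05) {
  speed <- sqrt(rowSums(velocity$values^2))
  n <- length(speed)
  fs <- velocity$fs
  nfft <- 2^(ceiling(log2(n)) + pad_level)
  k <- 0:(nfft / 2)
  mag <- vapply(k, function(kk) {
    Mod(sum(speed * exp(-2i * pi * kk * (0:(n - 1)) / nfft)))
  }, numeric(1))
  freq <- k * fs / nfft
  vhat <- mag / mag[1]
  sel <- which(freq <= fc_max)
  band <- seq_len(max(which(vhat[sel] >= amp_threshold)))
  f <- freq[band]; v <- vhat[band]
  -sum(sqrt((diff(f) / (f[length(f)] - f[1]))^2 + diff(v)^2))
}

test_that("SPARC matches a direct-DFT arc-length oracle on a minimum-jerk stroke", {
  mov <- min_jerk_segment(0.15, 1, fs = 100)
  got <- sparc(mov$velocity)
  expect_equal(got$sal, sparc_oracle(mov$velocity), tolerance = 1e-6)
  expect_lt(got$sal, 0)
  expect_lte(got$omega_c, 2 * pi * 20)
})

test_that("SPARC is amplitude- and rotation-invariant", {
  mov <- via_point_movement(2, seed = 4)
  v <- mov$velocity
  scaled <- kin_series(2 * v$values, v$fs, v$kind)
  expect_equal(sparc(scaled)$sal, sparc(v)$sal, tolerance = 1e-12)

  omega <- kin_series(v$values, v$fs, "angular_velocity")
  withr::with_seed(3, ang <- cumsum(rnorm(n_samples(v))) / 15)
  rot <- rot_from_euler_zyx(ang, -ang, ang / 3, v$fs)
  expect_equal(sparc(apply_rotation(omega, rot))$sal, sparc(omega)$sal,
               tolerance = 1e-12)
})

test_that("SPARC rejects degenerate and mis-specified inputs", {
  expect_error(sparc(const_series(c(0, 0, 0))), "identically zero")
  expect_error(sparc(const_series(c(1, 0, 0), kind = "acceleration")),
               "velocity")
  expect_error(sparc(const_series(c(1, 0, 0)), fc_max = 60), "Nyquist")
})

test_that("LDLJ-V matches the minimum-jerk closed form", {
  # v_peak = 1.875 A/T, integral ||jerk||^2 = 720 A^2/T^5
  # => -ln(720 / 1.875^2) = -ln(204.8)
  mov <- min_jerk_segment(0.15, 1, fs = 100)
  fit <- ldlj_v(mov$velocity)
  expect_equal(fit$value, -log(204.8), tolerance = 0.02)
  expect_equal(fit$peak, 1.875 * 0.15, tolerance = 1e-9)
  expect_equal(fit$duration, 1)
})

test_that("LDLJ-A matches the minimum-jerk closed form and ignores constant bias", {
  # a_peak = (10/sqrt(3)) A/T^2 => -ln(720 * 3 / 100) = -ln(21.6)
  mov <- min_jerk_segment(0.15, 1, fs = 100)
  fit <- ldlj_a(mov$acceleration)
  expect_equal(fit$value, -log(21.6), tolerance = 0.02)
  expect_equal(fit$peak, 10 / sqrt(3) * 0.15, tolerance = 1e-4)

  biased <- kin_series(sweep(mov$acceleration$values, 2, c(1.3, -0.4, 9.81), `+`),
                       mov$acceleration$fs, "acceleration")
  expect_equal(ldlj_a(biased)$value, fit$value, tolerance = 1e-9)

  expect_error(ldlj_a(const_series(c(1, 2, 3), kind = "acceleration")),
               "degenerate")
  expect_error(ldlj_a(mov$velocity), "acceleration")
})

test_that("LDLJ values are amplitude-invariant and duration-invariant", {
  mov <- via_point_movement(5, seed = 11)
  v <- mov$velocity
  scaled <- kin_series(3.7 * v$values, v$fs, v$kind)
  expect_equal(ldlj_v(scaled)$value, ldlj_v(v)$value, tolerance = 1e-9)

  base <- min_jerk_segment(0.15, 1, fs = 100)
  vals <- vapply(c(2.5, 5, 10, 20),
                 function(T) ldlj_v(time_scale(base, T)$velocity)$value,
                 numeric(1))
  # discretisation-limited agreement across a factor-8 duration range
  expect_lt(diff(range(vals)), 1.5e-3)
  expect_equal(vals[1], ldlj_v(base$velocity)$value, tolerance = 6e-3)

  sal <- vapply(c(2.5, 5, 10, 20),
                function(T) sparc(time_scale(mov, T)$velocity)$sal,
                numeric(1))
  expect_lt(diff(range(sal)) / abs(mean(sal)), 0.01)
  expect_lt(abs(mean(sal) - sparc(mov$velocity)$sal) / abs(mean(sal)), 0.01)
})

test_that("smoothness is invariant under a fixed rotation and translation of frame", {
  mov <- via_point_movement(2, seed = 21)
  q <- random_fixed_rotation(n_samples(mov$velocity), 100)
  v_rot <- apply_rotation(mov$velocity, q)
  a_rot <- apply_rotation(mov$acceleration, q)
  expect_equal(sparc(v_rot)$sal, sparc(mov$velocity)$sal, tolerance = 1e-9)
  expect_equal(ldlj_v(v_rot)$value, ldlj_v(mov$velocity)$value, tolerance = 1e-9)
  expect_equal(ldlj_a(a_rot)$value, ldlj_a(mov$acceleration)$value,
               tolerance = 1e-9)
})

test_that("LDLJ-A and LDLJ-V share the jerk integral up to the normaliser", {
  # with acceleration obtained by differentiating the velocity, both
  # measures integrate the identical jerk series, so
  # ldlj_a - ldlj_v = ln(T^2 a_peak^2 / v_peak^2) exactly
  mov <- via_point_movement(2, seed = 13)
  v <- mov$velocity
  a <- differentiate(v)
  fa <- ldlj_a(a)
  fv <- ldlj_v(v)
  expect_equal(fa$value - fv$value,
               log(fv$duration^2 * fa$peak^2 / fv$peak^2), tolerance = 1e-6)
})

test_that("median ground-truth smoothness decreases with via-point count", {
  seeds <- 1:15
  med <- function(n_via, fun) {
    stats::median(vapply(seeds, function(s) {
      m <- via_point_movement(n_via, seed = s)
      fun(m)
    }, numeric(1)))
  }
  for (fun in list(
    function(m) ldlj_v(m$velocity)$value,
    function(m) sparc(m$velocity)$sal,
    function(m) ldlj_a(m$acceleration)$value
  )) {
    vals <- vapply(c(1, 2, 5, 10), med, numeric(1), fun = fun)
    expect_true(all(diff(vals) < 0))
  }
})

test_that("tidy and glance methods return tibbles", {
  mov <- min_jerk_segment(0.15, 1, fs = 100)
  sp <- sparc(mov$velocity)
  expect_s3_class(tidy(sp), "tbl_df")
  expect_named(glance(sp), c("measure", "sal", "omega_c", "fc_hz"))
  lj <- ldlj_v(mov$velocity)
  expect_named(tidy(lj), c("measure", "value", "jerk_integral", "peak", "duration"))
})
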