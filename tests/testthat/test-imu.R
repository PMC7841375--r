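test_that("forward model reproduces the defining special cases", {
  g <- gravity_vector()
  n <- 101
  still <- list(acceleration = const_series(c(0, 0, 0), kind = "acceleration"),
                velocity = const_series(c(0, 0, 0)))

  # static sensor, identity orientation: accel reads g, gyro reads 0
  r0 <- forward_measure(still, rot_identity(n, 100), g)
  expect_equal(r0$accel$values, matrix(rep(unclass(g), each = n), ncol = 3))
  expect_equal(max(abs(r0$gyro$values)), 0)

  # free fall: accel reads 0 for any orientation
  fall <- list(acceleration = const_series(-unclass(g), kind = "acceleration"),
               velocity = const_series(c(0, 0, 0)))
  rf <- forward_measure(fall, random_fixed_rotation(n, 100), g)
  expect_lt(max(abs(rf$accel$values)), 1e-12)

  # identity orientation: accel = x'' + g exactly
  mov <- min_jerk_segment(0.15, 1, fs = 100)
  ri <- forward_measure(mov, rot_identity(n, 100), g)
  expect_equal(ri$accel$values,
               sweep(mov$acceleration$values, 2, unclass(g), `+`))
})

test_that("reconstruction round-trips the forward model with exact orientation", {
  g <- gravity_vector()
  mov <- via_point_movement(2, seed = 6)
  n <- n_samples(mov$acceleration)
  withr::with_seed(10, ang <- cumsum(rnorm(n)) / 30)
  true_rot <- rot_from_euler_zyx(ang, ang / 2, -ang, 100)
  reading <- forward_measure(mov, true_rot, g)
  lin <- reconstruct_linear(reading, g, truth = mov)
  expect_lt(max(abs(lin$accel_earth$values - mov$acceleration$values)), 1e-9)
  # discrete movement: final integrated velocity returns to zero
  expect_lt(max(abs(lin$velocity_earth$values[n, ])), 1e-6)
  expect_lt(max(abs(lin$delta_a$values)), 1e-9)
})

test_that("constant orientation error yields the closed-form bias and drift", {
  g <- gravity_vector()
  n <- 201
  still <- list(acceleration = kin_series(matrix(0, n, 3), 100, "acceleration"),
                velocity = kin_series(matrix(0, n, 3), 100, "velocity"))
  dR <- rz(25 * pi / 180)
  reading <- forward_measure(still, rot_identity(n, 100), g,
                             orientation_estimate = rot_series(dR, 100, n = n))
  lin <- reconstruct_linear(reading, g, truth = still)
  bias <- as.vector((dR - diag(3)) %*% unclass(g))
  expect_lt(max(abs(sweep(lin$accel_earth$values, 2, bias))), 1e-9)
  # velocity drifts linearly: |v(T)| = |(dR - I) g| * T
  T <- (n - 1) / 100
  expect_equal(sqrt(sum(lin$velocity_earth$values[n, ]^2)),
               sqrt(sum(bias^2)) * T, tolerance = 1e-9)

  # zero specific force read with an identity estimate: free-fall interpretation
  zr <- imu_reading(kin_series(matrix(0, n, 3), 100, "acceleration"),
                    kin_series(matrix(0, n, 3), 100, "angular_velocity"),
                    rot_identity(n, 100))
  zl <- reconstruct_linear(zr, g)
  expect_equal(zl$accel_earth$values,
               matrix(rep(-unclass(g), each = n), ncol = 3))
})

test_that("angular reconstruction preserves speed and isolates the error term", {
  mov <- via_point_movement(1, seed = 3)
  omega <- kin_series(mov$velocity$values, 100, "angular_velocity")
  n <- n_samples(omega)
  err <- orientation_error(25, duration(omega), 100, seed = 2)

  reading <- imu_reading(const_series(c(0, 0, 9.81), n = n, kind = "acceleration"),
                         omega, orientation_estimate = err$delta_R)
  ang <- reconstruct_angular(reading, truth_omega = omega)
  expect_equal(ang$omega_earth$values, apply_rotation(omega, err$delta_R)$values)
  expect_lt(max(abs(norm_series(ang$omega_earth) - norm_series(omega))), 1e-12)
  # delta_omega = (dR - I) omega
  expected <- apply_rotation(omega, err$delta_R)$values - omega$values
  expect_lt(max(abs(ang$delta_omega$values - expected)), 1e-12)

  # identity estimate: omega_earth equals the gyro channel
  ri <- imu_reading(reading$accel, omega, rot_identity(n, 100))
  expect_equal(reconstruct_angular(ri)$omega_earth$values, omega$values)

  expect_error(reconstruct_angular(imu_reading(reading$accel, omega)),
               "orientation estimate")
})

test_that("SGR is 0 in free fall, 1 at rest, and linear in the RMS norm", {
  g <- gravity_vector()
  expect_equal(sgr(const_series(c(0, 0, 0), kind = "acceleration"), g), 0)
  # static in an arbitrary orientation: |a| = |g| everywhere
  q <- random_fixed_rotation(101, 100)
  static <- apply_rotation(const_series(unclass(g), kind = "acceleration"),
                           rot_transpose(q))
  expect_equal(sgr(static, g), 1, tolerance = 1e-9)
  expect_equal(sgr(const_series(c(0, 0, 2 * 9.81), kind = "acceleration"), g), 2,
               tolerance = 1e-12)
  # orientation invariance: any rotation of the channel leaves SGR unchanged
  mov <- min_jerk_segment(0.15, 1, fs = 100)
  a_s <- kin_series(sweep(mov$acceleration$values, 2, unclass(g), `+`),
                    100, "acceleration")
  expect_equal(sgr(apply_rotation(a_s, q), g), sgr(a_s, g), tolerance = 1e-12)
})

test_that("a fixed body-to-earth rotation leaves all three measures unchanged", {
  g <- gravity_vector()
  mov <- via_point_movement(5, seed = 9)
  q <- random_fixed_rotation(n_samples(mov$velocity), 100)
  v_rot <- apply_rotation(mov$velocity, q)
  a_rot <- apply_rotation(mov$acceleration, q)
  omega <- kin_series(mov$velocity$values, 100, "angular_velocity")
  omega_rot <- kin_series(v_rot$values, 100, "angular_velocity")
  expect_equal(sparc(omega_rot)$sal, sparc(omega)$sal, tolerance = 1e-9)
  expect_equal(ldlj_v(omega_rot)$value, ldlj_v(omega)$value, tolerance = 1e-9)
  expect_equal(ldlj_a(a_rot)$value, ldlj_a(mov$acceleration)$value,
               tolerance = 1e-9)
})

test_that("IMU readings round-trip through the raw CSV schema", {
  g <- gravity_vector()
  mov <- min_jerk_segment(0.15, 1, fs = 100)
  n <- n_samples(mov$acceleration)
  withr::with_seed(17, {
    q <- matrix(rnorm(4 * n), ncol = 4)
  })
  q <- q / sqrt(rowSums(q^2))
  rot <- rot_from_quat(q, 100)
  reading <- forward_measure(mov, rot, g)
  df <- tibble::tibble(
    t = time_points(reading$accel),
    ax = reading$accel$values[, 1], ay = reading$accel$values[, 2],
    az = reading$accel$values[, 3],
    gx = reading$gyro$values[, 1], gy = reading$gyro$values[, 2],
    gz = reading$gyro$values[, 3],
    qw = q[, 1], qx = q[, 2], qy = q[, 3], qz = q[, 4]
  )
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(df, path)
  back <- read_imu_csv(path)
  expect_equal(back$accel$values, reading$accel$values, tolerance = 1e-6)
  expect_equal(back$orientation_estimate$r, rot$r, tolerance = 1e-6)
  # reconstruction through the stored estimate recovers the movement
  lin <- reconstruct_linear(back, g, truth = mov)
  expect_lt(max(abs(lin$accel_earth$values - mov$acceleration$values)), 1e-4)
})
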