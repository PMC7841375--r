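# shared fixtures, built in code

# constant-valued series
const_series <- function(v, n = 101, fs = 100, kind = "velocity") {
  kin_series(matrix(rep(v, each = n), ncol = 3), fs = fs, kind = kind)
}

# rotation matrix about z by `ang` radians
rz <- function(ang) {
  matrix(c(cos(ang), -sin(ang), 0, sin(ang), cos(ang), 0, 0, 0, 1),
         nrow = 3, byrow = TRUE)
}

# a random (seeded) constant-orientation rotation series
random_fixed_rotation <- function(n, fs, seed = 42) {
  withr::with_seed(seed, {
    q <- stats::rnorm(4)
  })
  rot_from_quat(matrix(q / sqrt(sum(q^2)), 1), fs = fs)$r |>
    matrix(nrow = 3, byrow = TRUE) |>
    rot_series(fs = fs, n = n)
}

# memoised full-grid run used by the acceptance checks: computed once per
# test session, at the default study configuration
acceptance_env <- new.env(parent = emptyenv())
acceptance_grid <- function() {
  if (is.null(acceptance_env$records)) {
    acceptance_env$records <- run_grid(grid_config(), seed = 20210114)
  }
  acceptance_env$records
}
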