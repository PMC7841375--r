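Package: imusmooth
Title: Movement Smoothness Estimation from Inertial Measurement Units
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimate movement smoothness of discrete human movements from
    inertial measurement unit (IMU) kinematics. Implements the spectral arc
    length (SPARC) and log dimensionless jerk computed from velocity (LDLJ-V)
    and from acceleration (LDLJ-A), a forward model of what an accelerometer
    and gyroscope measure for a movement with a fixed body frame, earth-frame
    reconstruction under error-bearing orientation estimates, the
    sensor-to-gravity ratio (SGR), a minimum-jerk via-point movement simulator
    with stochastic orientation-error rotation series, and a factorial
    simulation pipeline that quantifies when each smoothness measure can be
    trusted.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
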