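Package: gaittraj
Title: Stride-Wise Foot Trajectory Estimation from Shoe-Mounted Inertial Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs per-stride foot trajectories from calibrated,
    stride-segmented inertial measurement unit (IMU) data recorded at the shoe.
    Implements three quaternion orientation estimators (first-order gyroscope
    integration, a magnetometer-free Madgwick complementary filter and an
    Euston/Mahony-style explicit complementary filter), gravity removal with
    piecewise-linear dedrifting, and three zero-velocity-update double
    integration schemes (direct integration with linear dedrifting, fusion of
    direct and time-reversed integrals with a sigmoid weight, and analytic
    integration in zero-DC Fourier and B-spline bases). A synthetic gait
    simulator provides exact ground-truth trajectories and orientations for
    validation, and a benchmarking harness provides pooled error distributions,
    range-normalised grid search over filter parameters and method ranking.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    splines,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
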