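# Synthetic gait simulator: closed-form strides with exact ground-truth
# position, velocity and orientation, and the noisy sensor-frame IMU signals
# an ideal shoe-mounted sensor would record for them.

#' Specify a synthetic stride
#'
#' Defines a stride between two consecutive mid-stances satisfying every
#' boundary condition the estimators assume: the foot is stationary (zero
#' velocity and zero movement acceleration) at both ends, the floor is level
#' (equal vertical position at both ends), and stance is quasi-static. The
#' horizontal profile is a minimum-jerk reach of `stride_length`; clearance
#' is a smooth two-lobe (double-hump) profile peaking at `max_clearance`;
#' orientation follows a sagittal plantarflexion-dorsiflexion cycle on top
#' of a static mounting tilt. Defaults emulate normal-paced healthy gait
#' recorded with a calibrated consumer-grade IMU.
#'
#' @param stride_length Horizontal displacement in m. Default 1.2.
#' @param stride_duration Mid-stance to mid-stance duration in s. Default 1.1.
#' @param max_clearance Peak sensor clearance in m. Default 0.12.
#' @param stance_fraction Fraction of the stride that is quasi-static
#'   (split between the stance halves at either end). Default 0.55.
#' @param sampling_rate Output IMU rate in Hz. Default 102.4.
#' @param accel_noise_sd Accelerometer white-noise SD in g. Default 0.01.
#' @param gyro_noise_sd Gyroscope white-noise SD in rad/s. Default 0.01.
#' @param gyro_bias Length-3 constant gyroscope bias in rad/s.
#'   Default c(0.01, -0.005, 0.008), about 0.8 deg/s overall.
#' @param accel_bias Length-3 constant sensor-frame accelerometer bias in g.
#'   Default zero; non-zero values inject the constant acceleration drift
#'   used in drift-robustness experiments.
#' @param initial_tilt Mounting tilt in degrees, `c(x = ..., z = ...)`,
#'   about the anterior-posterior and transversal axes. Default c(5, 10).
#' @param pitch_amplitude Sagittal rotation amplitude in degrees. Default 40.
#' @param lateral_amplitude Peak medio-lateral sway in m. Default 0.02.
#' @param wobble_amplitude Amplitude of the small frontal/transversal
#'   rotation wobble in degrees. Default 5.
#' @param seed Integer seed making the sensor noise reproducible.
#' @return A list of class `synthetic_stride_spec`.
#' @export
synthetic_stride_spec <- function(stride_length = 1.2, stride_duration = 1.1,
                                  max_clearance = 0.12, stance_fraction = 0.55,
                                  sampling_rate = 102.4,
                                  accel_noise_sd = 0.01, gyro_noise_sd = 0.01,
                                  gyro_bias = c(0.01, -0.005, 0.008),
                                  accel_bias = c(0, 0, 0),
                                  initial_tilt = c(x = 5, z = 10),
                                  pitch_amplitude = 40,
                                  lateral_amplitude = 0.02,
                                  wobble_amplitude = 5,
                                  seed = 1L) {
  stopifnot(
    stride_length >= 0, stride_duration > 0, max_clearance >= 0,
    stance_fraction > 0, stance_fraction < 1, sampling_rate > 0,
    accel_noise_sd >= 0, gyro_noise_sd >= 0,
    length(gyro_bias) == 3, length(accel_bias) == 3, length(initial_tilt) == 2
  )
  structure(
    list(stride_length = stride_length, stride_duration = stride_duration,
         max_clearance = max_clearance, stance_fraction = stance_fraction,
         sampling_rate = sampling_rate, accel_noise_sd = accel_noise_sd,
         gyro_noise_sd = gyro_noise_sd, gyro_bias = as.numeric(gyro_bias),
         accel_bias = as.numeric(accel_bias),
         initial_tilt = as.numeric(initial_tilt),
         pitch_amplitude = pitch_amplitude,
         lateral_amplitude = lateral_amplitude,
         wobble_amplitude = wobble_amplitude, seed = as.integer(seed)),
    class = "synthetic_stride_spec"
  )
}

# Minimum-jerk unit profile and derivatives on tau in [0, 1].
minjerk <- function(tau, deriv = 0) {
  switch(as.character(deriv),
    "0" = 10 * tau^3 - 15 * tau^4 + 6 * tau^5,
    "1" = 30 * tau^2 - 60 * tau^3 + 30 * tau^4,
    "2" = 60 * tau - 180 * tau^2 + 120 * tau^3
  )
}

# Two-lobe clearance profile on tau in [0, 1]: sin^4 envelope times a
# centre dip; value, first and second derivatives vanish at both ends and
# the curve has exactly two maxima. Normalised to peak 1.
clearance_profile <- function(tau, deriv = 0) {
  b <- 0.8
  peak <- (2 / (3 * b))^2 * (1 - b * 2 / (3 * b)) # g(u*) with u* = 2/(3b)
  s <- sin(pi * tau); cs <- cos(pi * tau)
  u <- s^2
  up <- 2 * pi * s * cs                  # du/dtau
  upp <- 2 * pi^2 * (cs^2 - s^2)         # d2u/dtau2
  g <- u^2 * (1 - b * u)
  dg <- 2 * u - 3 * b * u^2              # dg/du
  d2g <- 2 - 6 * b * u
  switch(as.character(deriv),
    "0" = g / peak,
    "1" = dg * up / peak,
    "2" = (d2g * up^2 + dg * upp) / peak
  )
}

# Sagittal pitch profile on tau in [0, 1] (radians, amplitude A): one
# plantarflexion-dorsiflexion cycle, zero with zero slope at both ends.
pitch_profile <- function(tau, A, deriv = 0) {
  s2 <- sin(2 * pi * tau); c2 <- cos(2 * pi * tau)
  s <- sin(pi * tau); cs <- cos(pi * tau)
  if (deriv == 0) return(A * s2 * s^2)
  A * (2 * pi * c2 * s^2 + s2 * 2 * pi * s * cs)
}

# Single-lobe lateral sway profile: value, first and second derivative all
# vanish at both ends (sin^4 envelope), returning to the line of progression.
lateral_profile <- function(tau, deriv = 0) {
  s <- sin(pi * tau); cs <- cos(pi * tau)
  switch(as.character(deriv),
    "0" = s^4,
    "1" = 4 * pi * s^3 * cs,
    "2" = 4 * pi^2 * (3 * s^2 * cs^2 - s^4)
  )
}

#' Closed-form ground truth for a synthetic stride
#'
#' @param spec A [synthetic_stride_spec()].
#' @return List with `truth`, a tibble over the output sample grid
#'   (`time_s, sx, sy, sz, vx, vy, vz, awx_mps2, awy_mps2, awz_mps2,
#'   qw, qx, qy, qz, in_movement`), and helper closures used internally.
#' @export
make_ground_truth <- function(spec) {
  fs <- spec$sampling_rate
  T_str <- spec$stride_duration
  n <- round(T_str * fs) + 1L
  dt <- 1 / fs
  time <- (seq_len(n) - 1) * dt
  # movement window (swing plus push-off/landing transients)
  t_a <- T_str * spec$stance_fraction / 2
  t_b <- T_str - t_a
  Tm <- t_b - t_a
  tau <- pmin(pmax((time - t_a) / Tm, 0), 1)
  in_move <- time > t_a & time < t_b

  sx <- spec$stride_length * minjerk(tau)
  vx <- spec$stride_length * minjerk(tau, 1) / Tm
  ax <- spec$stride_length * minjerk(tau, 2) / Tm^2
  sy <- spec$max_clearance * clearance_profile(tau)
  vy <- spec$max_clearance * clearance_profile(tau, 1) / Tm
  ay <- spec$max_clearance * clearance_profile(tau, 2) / Tm^2
  sz <- spec$lateral_amplitude * lateral_profile(tau)
  vz <- spec$lateral_amplitude * lateral_profile(tau, 1) / Tm
  az <- spec$lateral_amplitude * lateral_profile(tau, 2) / Tm^2
  # endpoints clamp exactly
  vx[!in_move] <- 0; ax[!in_move] <- 0
  vy[!in_move] <- 0; ay[!in_move] <- 0
  vz[!in_move] <- 0; az[!in_move] <- 0
  sx[time >= t_b] <- spec$stride_length
  sy[time >= t_b] <- 0
  sz[time >= t_b] <- 0

  A <- spec$pitch_amplitude * pi / 180
  W <- spec$wobble_amplitude * pi / 180
  tilt_x <- spec$initial_tilt[1] * pi / 180
  tilt_z <- spec$initial_tilt[2] * pi / 180
  q0 <- quat_conjugate(quat_multiply(
    quat_from_axis_angle(c(0, 0, 1), tilt_z),
    quat_from_axis_angle(c(1, 0, 0), tilt_x)
  ))
  # orientation at an arbitrary instant: sagittal cycle plus small
  # transversal/frontal wobble in the world frame on top of the mounting tilt
  q_of <- function(t) {
    ta <- pmin(pmax((t - t_a) / Tm, 0), 1)
    qz <- quat_from_axis_angle(c(0, 0, 1), pitch_profile(ta, A))
    qx <- quat_from_axis_angle(c(1, 0, 0), pitch_profile(ta, W))
    qy <- quat_from_axis_angle(c(0, 1, 0), 0.6 * W * sin(pi * ta)^2)
    quat_multiply(qz, quat_multiply(qx, quat_multiply(qy, q0)))
  }
  # body angular rate from central quaternion differences at a step well
  # below the sampling interval (discretisation error far below estimator
  # error): q(t+h) = q(t) (x) exp(0.5 (0, omega) h)
  h <- 1 / (20 * fs)
  q <- matrix(NA_real_, n, 4)
  omega <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    q[i, ] <- q_of(time[i])
    dq <- quat_multiply(quat_conjugate(q_of(time[i] - h)), q_of(time[i] + h))
    vn <- sqrt(sum(dq[2:4]^2))
    if (vn > 0) {
      omega[i, ] <- dq[2:4] / vn * (2 * atan2(vn, dq[1])) / (2 * h)
    }
  }
  truth <- tibble::tibble(
    time_s = time,
    sx = sx, sy = sy, sz = sz,
    vx = vx, vy = vy, vz = vz,
    awx_mps2 = ax, awy_mps2 = ay, awz_mps2 = az,
    qw = q[, 1], qx = q[, 2], qy = q[, 3], qz = q[, 4],
    wx = omega[, 1], wy = omega[, 2], wz = omega[, 3],
    in_movement = in_move
  )
  list(truth = truth, spec = spec)
}

#' Synthesize the IMU recording for a ground-truth stride
#'
#' Inverts the pipeline's measurement model: the world-frame specific force
#' `a_world / g + (0, 1, 0)` is rotated into the sensor frame with the
#' conjugate orientation; the body angular rate comes from quaternion
#' differences of the closed-form orientation at a time step well below the
#' sampling interval. Gaussian noise and constant biases are added with the spec's seed
#' (deterministic per seed; the caller's RNG state is left untouched).
#'
#' @param truth Output of [make_ground_truth()].
#' @param spec A [synthetic_stride_spec()]; defaults to the one in `truth`.
#' @return A [stride_recording()] whose mid-stance anchors are the first and
#'   last sample.
#' @export
imu_from_ground_truth <- function(truth, spec = truth$spec) {
  tt <- truth$truth
  n <- nrow(tt)
  g_mag <- 9.81
  gyro <- matrix(NA_real_, n, 3)
  accel <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    q <- c(tt$qw[i], tt$qx[i], tt$qy[i], tt$qz[i])
    Rt <- t(quat_to_matrix(q))
    f_world <- c(tt$awx_mps2[i], tt$awy_mps2[i], tt$awz_mps2[i]) / g_mag + c(0, 1, 0)
    accel[i, ] <- Rt %*% f_world
    gyro[i, ] <- c(tt$wx[i], tt$wy[i], tt$wz[i]) # already a body rate
  }
  noise <- with_local_seed(spec$seed, {
    list(
      g = matrix(stats::rnorm(3 * n, sd = spec$gyro_noise_sd), n, 3),
      a = matrix(stats::rnorm(3 * n, sd = spec$accel_noise_sd), n, 3)
    )
  })
  gyro <- gyro + noise$g + matrix(spec$gyro_bias, n, 3, byrow = TRUE)
  accel <- accel + noise$a + matrix(spec$accel_bias, n, 3, byrow = TRUE)
  stride_recording(
    tibble::tibble(
      time_s = tt$time_s,
      gx = gyro[, 1], gy = gyro[, 2], gz = gyro[, 3],
      ax = accel[, 1], ay = accel[, 2], az = accel[, 3]
    ),
    i_ms_start = 1L, i_ms_end = n, delta_t = 1 / spec$sampling_rate
  )
}

#' Simulate one stride
#'
#' @param spec A [synthetic_stride_spec()].
#' @return List of class `synthetic_stride` with `recording` (the noisy
#'   [stride_recording()]), `truth` (ground-truth tibble) and `spec`.
#' @export
simulate_stride <- function(spec = synthetic_stride_spec()) {
  gt <- make_ground_truth(spec)
  structure(
    list(recording = imu_from_ground_truth(gt, spec), truth = gt$truth,
         spec = spec),
    class = "synthetic_stride"
  )
}

#' Simulate a reproducible stride dataset
#'
#' Draws stride lengths and durations uniformly from the requested ranges
#' (emulating walking trials with low, normal and high stride length and
#' velocity regimes) and simulates each stride with an independent
#' seed derived from `seed`.
#'
#' @param n_strides Number of strides.
#' @param stride_length_range,stride_duration_range Ranges to span.
#' @param seed Integer master seed.
#' @param ... Further arguments passed to [synthetic_stride_spec()].
#' @return Tibble with one row per stride: `stride_id`, the drawn
#'   parameters, and list-columns `recording`, `truth`, `spec`.
#' @export
simulate_dataset <- function(n_strides = 20,
                             stride_length_range = c(0.5, 1.8),
                             stride_duration_range = c(0.9, 1.4),
                             seed = 1L, ...) {
  draws <- with_local_seed(seed, {
    tibble::tibble(
      stride_length = stats::runif(n_strides, stride_length_range[1],
                                   stride_length_range[2]),
      stride_duration = stats::runif(n_strides, stride_duration_range[1],
                                     stride_duration_range[2])
    )
  })
  strides <- purrr::map(seq_len(n_strides), function(i) {
    spec <- synthetic_stride_spec(
      stride_length = draws$stride_length[i],
      stride_duration = draws$stride_duration[i],
      max_clearance = 0.08 + 0.04 * draws$stride_length[i] / 1.5,
      seed = as.integer(seed) + i,
      ...
    )
    simulate_stride(spec)
  })
  tibble::tibble(
    stride_id = seq_len(n_strides),
    stride_length = draws$stride_length,
    stride_duration = draws$stride_duration,
    recording = purrr::map(strides, "recording"),
    truth = purrr::map(strides, "truth"),
    spec = purrr::map(strides, "spec")
  )
}

#' Write a simulated dataset to per-stride CSV files
#'
#' Writes the stride CSV, events CSV and a ground-truth CSV
#' (`time_s, sx, sy, sz, vx, vy, vz, qw, qx, qy, qz`) per stride.
#'
#' @param dataset Output of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset_csv <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(dataset))) {
    id <- sprintf("stride_%03d", dataset$stride_id[i])
    write_stride_csv(dataset$recording[[i]],
                     file.path(dir, paste0(id, ".csv")),
                     file.path(dir, paste0(id, "_events.csv")))
    truth <- dataset$truth[[i]][c("time_s", "sx", "sy", "sz", "vx", "vy", "vz",
                                  "qw", "qx", "qy", "qz")]
    readr::write_csv(truth, file.path(dir, paste0(id, "_truth.csv")))
  }
  invisible(dir)
}

# Evaluate `expr` under a fixed seed, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}
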