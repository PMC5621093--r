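test_that("accelerometer gating enforces the gravity band and swing suppression", {
  expect_true(accel_gate(c(0, 1, 0), gamma = 0.04, in_swing = FALSE))
  expect_false(accel_gate(c(0, 1.05, 0), gamma = 0.04, in_swing = FALSE))
  expect_true(accel_gate(c(0, 1.25, 0), gamma = 0.25, in_swing = FALSE)) # band edge
  expect_false(accel_gate(c(0, 1, 0), gamma = 10, in_swing = TRUE))
})

test_that("gyroscope integration reproduces constant-rate rotations", {
  s0 <- constant_stride(n = 50)
  track <- estimate_orientation(s0, "gyro")
  q <- as.matrix(track[, c("qw", "qx", "qy", "qz")])
  expect_true(all(abs(q - matrix(quat_identity(), 50, 4, byrow = TRUE)) < 1e-12))
  expect_false(any(track$accel_update))

  omega0 <- 1.2
  s1 <- constant_stride(n = 103, gyro = c(0, 0, omega0))
  tr <- estimate_orientation(s1, "gyro", swing = rep(FALSE, 103))
  qn <- unlist(tr[103, c("qw", "qx", "qy", "qz")])
  T_str <- 102 * s1$delta_t
  expect_lt(quat_angle(qn, quat_from_axis_angle(c(0, 0, 1), omega0 * T_str)),
            omega0 * T_str * (omega0 * s1$delta_t)^2) # first-order integrator
  # unit norm everywhere
  expect_equal(rowSums(as.matrix(tr[, c("qw", "qx", "qy", "qz")])^2),
               rep(1, 103), tolerance = 1e-9)
})

test_that("the gravity-prediction Jacobian matches central finite differences", {
  qs <- random_unit_quats(200, seed = 17)
  h <- 1e-6
  for (i in seq_len(nrow(qs))) {
    q <- qs[i, ]
    J <- gaittraj:::specific_force_jacobian(q)
    J_fd <- matrix(NA_real_, 3, 4)
    for (j in 1:4) {
      qp <- q; qm <- q
      qp[j] <- qp[j] + h; qm[j] <- qm[j] - h
      J_fd[, j] <- (gaittraj:::predict_specific_force(qp) -
                      gaittraj:::predict_specific_force(qm)) / (2 * h)
    }
    expect_true(max(abs(J - J_fd)) < 1e-6)
  }
})

test_that("zero-gain filters reduce exactly to gyroscope integration", {
  s <- simulate_stride(synthetic_stride_spec(seed = 9))$recording
  base <- estimate_orientation(s, "gyro")
  mad <- estimate_orientation(s, "madgwick", madgwick_params(beta = 0, gamma = 0.24))
  eus <- estimate_orientation(s, "euston", euston_params(k_p = 0, k_i = 0))
  cols <- c("qw", "qx", "qy", "qz")
  expect_identical(as.matrix(base[cols]), as.matrix(mad[cols]))
  expect_identical(as.matrix(base[cols]), as.matrix(eus[cols]))
})

test_that("a zero-error accelerometer leaves the Madgwick step at the gyro step", {
  q <- quat_from_axis_angle(c(1, 0, 0), 0.3)
  accel <- gaittraj:::predict_specific_force(q) # measured = predicted
  omega <- c(0.2, -0.1, 0.4)
  dt <- 0.01
  stepped <- madgwick_step(q, omega, accel, madgwick_params(beta = 0.1, gamma = 1),
                           use_accel = TRUE, delta_t = dt)
  gyro_only <- quat_normalize(q + quat_derivative(q, omega) * dt)
  expect_equal(stepped, gyro_only, tolerance = 1e-9)
})

test_that("the Euston error term measures the gravity mismatch and converges", {
  # aligned prediction and measurement: e = 0, step equals gyro step
  q <- quat_from_axis_angle(c(0, 0, 1), 0.2)
  accel <- gaittraj:::predict_specific_force(q)
  st0 <- list(integral = c(0, 0, 0), e_prev = c(0, 0, 0))
  out <- euston_step(q, c(0, 0, 0), accel, euston_params(k_p = 1, k_i = 0),
                     use_accel = TRUE, integ_state = st0, delta_t = 0.01)
  expect_equal(out$q, q, tolerance = 1e-12)

  # constant mismatch theta, omega = 0, kI = 0: scalar ODE phi' = -kP sin(phi),
  # so the tilt error decays approximately as phi0 * exp(-kP t)
  kp <- 1
  dt <- 1e-3
  phi0 <- 0.2
  q <- quat_from_axis_angle(c(0, 0, 1), phi0) # estimate tilted; truth identity
  accel <- c(0, 1, 0)
  st <- st0
  e1 <- NULL
  for (i in seq_len(2000)) {
    out <- euston_step(q, c(0, 0, 0), accel, euston_params(k_p = kp, k_i = 0),
                       use_accel = TRUE, integ_state = st, delta_t = dt)
    if (i == 1) e1 <- out$integ_state$e_prev
    q <- out$q; st <- out$integ_state
  }
  expect_equal(sqrt(sum(e1^2)), sin(phi0), tolerance = 1e-6)
  phi_end <- quat_angle(q, quat_identity())
  expect_equal(phi_end, phi0 * exp(-kp * 2), tolerance = 0.05)
})

test_that("the integral gain corrects a constant gyroscope bias", {
  bias <- c(0, 0, 0.05)
  s <- constant_stride(n = 400, gyro = bias) # truth: constant attitude
  p_noI <- euston_params(k_p = 0.5, k_i = 0, gamma = 0.1)
  p_I <- euston_params(k_p = 0.5, k_i = 0.5, gamma = 0.1)
  err <- function(track) {
    q <- unlist(track[nrow(track), c("qw", "qx", "qy", "qz")])
    quat_angle(q, quat_identity())
  }
  e_noI <- err(estimate_orientation(s, "euston", p_noI))
  e_I <- err(estimate_orientation(s, "euston", p_I))
  expect_lt(e_I, e_noI)
})

test_that("trackers follow the simulator ground truth when the gyro is clean", {
  max_err <- function(fs, m) {
    sim <- simulate_stride(clean_spec(sampling_rate = fs, seed = 4))
    track <- estimate_orientation(sim$recording, m)
    qt <- as.matrix(sim$truth[, c("qw", "qx", "qy", "qz")])
    qe <- as.matrix(track[, c("qw", "qx", "qy", "qz")])
    max(vapply(seq_len(nrow(qt)),
               function(i) quat_angle(qe[i, ], qt[i, ]), numeric(1)))
  }
  for (m in c("gyro", "madgwick", "euston")) {
    e_lo <- max_err(102.4, m)
    e_hi <- max_err(204.8, m)
    # first-order integrator: angle error O(delta_t * T), shrinking with dt
    expect_lt(e_lo, 0.06)
    expect_lt(e_hi, e_lo)
  }
})

test_that("stance update coverage grows monotonically with the gamma band", {
  sim <- simulate_stride(synthetic_stride_spec(seed = 8))
  fracs <- vapply(default_param_grids()$gamma, function(g) {
    tr <- estimate_orientation(sim$recording, "madgwick",
                               madgwick_params(beta = 0.046, gamma = g))
    stance_update_fraction(tr)
  }, numeric(1))
  expect_true(all(diff(fracs) >= 0))
  # unbounded band with no swing: every stance sample updates
  s0 <- constant_stride(n = 30)
  tr <- estimate_orientation(s0, "madgwick", madgwick_params(0.046, Inf))
  expect_equal(stance_update_fraction(tr, rep(TRUE, 30)), 1.0)
  # zero band on noisy data: almost surely no updates
  noisy <- simulate_stride(synthetic_stride_spec(seed = 10))$recording
  tr0 <- estimate_orientation(noisy, "madgwick", madgwick_params(0.046, 0))
  expect_equal(stance_update_fraction(tr0), 0)
})
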