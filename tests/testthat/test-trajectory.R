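test_that("world-frame transform preserves norms and inverts cleanly", {
  n <- 25
  ident <- tibble::tibble(qw = rep(1, n), qx = 0, qy = 0, qz = 0)
  set.seed(51)
  acc <- matrix(rnorm(3 * n), n, 3)
  out <- to_world(ident, acc)
  expect_equal(as.matrix(out), acc, ignore_attr = TRUE)

  qs <- random_unit_quats(n, seed = 52)
  track <- tibble::tibble(qw = qs[, 1], qx = qs[, 2], qy = qs[, 3], qz = qs[, 4])
  aw <- as.matrix(to_world(track, acc))
  expect_equal(sqrt(rowSums(aw^2)), sqrt(rowSums(acc^2)), tolerance = 1e-9)
  # static tilted pose with the exact quaternion: world reading is (0, 1, 0)
  q <- initial_orientation(as.numeric(rot_z(0.3) %*% rot_x(-0.2) %*% c(0, 1, 0)))
  a_s <- matrix(quat_rotate(quat_conjugate(q), c(0, 1, 0)), 10, 3, byrow = TRUE)
  tq <- tibble::tibble(qw = q[1], qx = q[2], qy = q[3], qz = q[4], .rows = 10)
  expect_equal(as.matrix(to_world(tq, a_s)),
               matrix(c(0, 1, 0), 10, 3, byrow = TRUE),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("gravity removal zeroes a static stride and the stride endpoints", {
  n <- 40
  static <- matrix(c(0, 1, 0), n, 3, byrow = TRUE)
  a <- remove_gravity(static)
  expect_true(all(abs(as.matrix(a)) < 1e-12))

  # constant offset on one axis: endpoints forced to zero
  off <- static; off[, 1] <- off[, 1] + 0.05
  a2 <- as.matrix(remove_gravity(off))
  expect_equal(unname(a2[1, ]), c(0, 0, 0))
  expect_equal(unname(a2[n, ]), c(0, 0, 0))

  # single-line variant matches the closed-form interpolated correction
  set.seed(61)
  noisy <- static + matrix(rnorm(3 * n, sd = 0.02), n, 3)
  a3 <- as.matrix(remove_gravity(noisy, dedrift = "linear"))
  raw <- (noisy - static) * 9.81
  idx <- (seq_len(n) - 1) / (n - 1)
  for (ax in 1:3) {
    expected <- raw[, ax] - (raw[1, ax] + (raw[n, ax] - raw[1, ax]) * idx)
    expect_equal(unname(a3[, ax]), expected, tolerance = 1e-12)
  }
})

test_that("trapezoidal cumulative integration is exact for polynomials up to degree 1", {
  dt <- 0.01
  n <- 101
  expect_equal(trapezoid_cumint(rep(3, n), dt)[n], 3 * (n - 1) * dt)
  expect_equal(trapezoid_cumint(rep(0, n), dt), rep(0, n))
  t <- (seq_len(n) - 1) * dt
  ramp <- 2 * t + 1
  expect_equal(trapezoid_cumint(ramp, dt), t^2 + t, tolerance = 1e-12)
})

test_that("linear dedrifting pins the endpoints and removes pure lines", {
  t <- seq(0, 1, length.out = 51)
  y0 <- sin(2 * pi * t) # already zero at both ends
  expect_equal(linear_dedrift(y0), y0, tolerance = 1e-12)
  expect_equal(linear_dedrift(3 * t + 2), rep(0, 51), tolerance = 1e-12)
  y <- sin(pi * t) + 0.3 * t
  d <- linear_dedrift(y)
  expect_identical(d[c(1, 51)], c(0, 0))
  expect_equal(d, sin(pi * t) - sin(pi) * t, tolerance = 1e-12)
})

test_that("time reversal is an involution that preserves the full-span integral", {
  set.seed(71)
  a <- matrix(rnorm(90), 30, 3)
  expect_equal(reverse_accel(reverse_accel(a)), a)
  sym <- matrix(rep(cos(seq(-1, 1, length.out = 30)), 3), 30, 3) # even signal
  expect_equal(reverse_accel(sym), -sym)
  dt <- 0.01
  for (ax in 1:3) {
    fwd <- trapezoid_cumint(a[, ax], dt)
    # change of variables: the full-span integral of the flipped-and-negated
    # signal is the negative of the original full-span integral
    rev_int <- trapezoid_cumint(-rev(a[, ax]), dt)
    expect_equal(rev_int[30], -fwd[30], tolerance = 1e-12)
  }
})

test_that("sigmoid fusion weights are exact at the endpoints and monotone", {
  w <- sigmoid_weight(120, t0 = 0.6, eta = 0.08)
  expect_identical(w[1], 0)
  expect_identical(w[120], 1)
  expect_true(all(diff(w) >= 0))
  # unnormalised sigmoid is 1/2 at its midpoint
  h <- function(tau, t0, eta) 1 / (1 + exp(-(tau - t0) / eta))
  expect_equal(h(0.6, 0.6, 0.08), 0.5)
  # large eta approaches the linear ramp
  w_inf <- sigmoid_weight(120, t0 = 0.5, eta = 1e6)
  expect_equal(w_inf, seq(0, 1, length.out = 120), tolerance = 1e-6)
})

test_that("direct integration honours the zero-velocity and level-floor conditions", {
  n <- 80
  dt <- 1 / 102.4
  zero <- structure(tibble::tibble(ax_w = rep(0, n), ay_w = 0, az_w = 0))
  tr <- integrate_direct(zero, dt)
  expect_true(all(abs(as.matrix(tr[, -1])) == 0))

  # constant bias: dedrifting still zeroes the velocity endpoints exactly
  bias <- tibble::tibble(ax_w = rep(0.4, n), ay_w = -0.2, az_w = 0.1)
  tr2 <- integrate_direct(bias, dt)
  expect_identical(unlist(tr2[c(1, n), c("vx", "vy", "vz")]),
                   setNames(rep(0, 6), c("vx1", "vx2", "vy1", "vy2", "vz1", "vz2")))
  expect_identical(tr2$sy[c(1, n)], c(0, 0))
})

test_that("direct & reverse fusion equals direct integration for drift-free signals", {
  n <- 129
  dt <- 1 / 102.4
  t <- (seq_len(n) - 1) * dt
  T_str <- t[n]
  a1 <- sin(2 * pi * t / T_str) # integral returns to zero: no drift
  a <- tibble::tibble(ax_w = a1, ay_w = 0.5 * a1, az_w = 0)
  dr <- integrate_direct_reverse(a, dt, t0 = 0.6, eta = 0.08)
  fwd <- trapezoid_cumint(a1, dt)
  expect_equal(dr$vx, fwd, tolerance = 1e-9)

  # constant bias: endpoints are anchored without explicit dedrifting
  ab <- tibble::tibble(ax_w = a1 + 0.3, ay_w = 0.5 * a1 - 0.2, az_w = 0.1)
  dr2 <- integrate_direct_reverse(ab, dt)
  expect_identical(unlist(dr2[c(1, n), c("vx", "vy", "vz")]),
                   setNames(rep(0, 6), c("vx1", "vx2", "vy1", "vy2", "vz1", "vz2")))
  expect_identical(dr2$sy[c(1, n)], c(0, 0))
})

test_that("stride length is invariant under a global heading rotation", {
  sim <- simulate_stride(synthetic_stride_spec(seed = 13))
  fit <- run_pipeline(sim$recording, "gyro", integ_method = "direct")
  a <- as.matrix(fit$accel_world[, c("ax_w", "ay_w", "az_w")])
  Rh <- rot_y(0.8) # heading rotation about the world vertical
  a_rot <- t(Rh %*% t(a))
  tr <- integrate_direct(tibble::tibble(ax_w = a_rot[, 1], ay_w = a_rot[, 2],
                                        az_w = a_rot[, 3]),
                         attr(fit$trajectory, "delta_t"))
  n <- nrow(tr)
  L_rot <- sqrt(tr$sx[n]^2 + tr$sz[n]^2)
  expect_equal(L_rot, fit$summary$stride_length_m, tolerance = 1e-9)
})

test_that("all three integrators agree in the ideal high-rate limit", {
  # drift-free band-limited acceleration sampled at 1 kHz
  n <- 1001
  dt <- 1e-3
  t <- (seq_len(n) - 1) * dt
  T_str <- t[n]
  base <- 0.4 * sin(2 * pi * t / T_str) + 0.15 * sin(4 * pi * t / T_str)
  # the vertical component must also be drift-free through the second
  # integration stage: zero-mean velocity, so the floor is met again at the end
  a <- tibble::tibble(ax_w = base, ay_w = 0.3 * cos(2 * pi * t / T_str), az_w = 0)
  p <- analytic_params(n_fourier = 8, smoothness = 1e-8)
  trs <- list(
    integrate_direct(a, dt),
    integrate_direct_reverse(a, dt),
    integrate_analytic(a, dt, p)
  )
  for (i in 2:3) {
    for (v in c("vx", "vy", "vz", "sx", "sy", "sz")) {
      expect_lt(max(abs(trs[[i]][[v]] - trs[[1]][[v]])), 1e-6)
    }
  }
})

test_that("the best pipeline recovers stride length under realistic noise", {
  errs <- c()
  for (L in c(0.5, 1.0, 1.5)) {
    for (seed in 1:7) {
      spec <- synthetic_stride_spec(stride_length = L, seed = 100 * seed + L * 10)
      sim <- simulate_stride(spec)
      fit <- run_pipeline(sim$recording, "madgwick", integ_method = "direct_reverse")
      errs <- c(errs, abs(fit$summary$stride_length_m - L) / L)
    }
  }
  expect_lt(median(errs), 0.05)
})
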