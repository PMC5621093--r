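test_that("plane angles invert the z-x-y Euler construction", {
  set.seed(81)
  for (i in 1:15) {
    a <- runif(1, -1.2, 1.2) # sagittal, about z
    b <- runif(1, -0.8, 0.8) # transversal, about x
    c_ <- runif(1, -1.2, 1.2) # frontal, about y
    q <- quat_multiply(quat_from_axis_angle(c(0, 0, 1), a),
                       quat_multiply(quat_from_axis_angle(c(1, 0, 0), b),
                                     quat_from_axis_angle(c(0, 1, 0), c_)))
    ang <- plane_angles(tibble::tibble(qw = q[1], qx = q[2], qy = q[3], qz = q[4]))
    expect_equal(ang$sagittal_deg, a * 180 / pi, tolerance = 1e-9)
    expect_equal(ang$transversal_deg, b * 180 / pi, tolerance = 1e-9)
    expect_equal(ang$frontal_deg, c_ * 180 / pi, tolerance = 1e-9)
  }
})

test_that("pooled error moments define accuracy and precision", {
  d0 <- pooled_errors(list(c(1, 2), c(3)), list(c(1, 2), c(3)))
  ap0 <- accuracy_precision(d0)
  expect_equal(ap0$accuracy, 0)
  expect_equal(ap0$precision, 0)
  ap1 <- accuracy_precision(c(-1, 1))
  expect_equal(ap1$accuracy, 0)
  expect_equal(ap1$precision, sd(c(-1, 1)))
  # pooling is order-free
  e1 <- pooled_errors(list(c(1, 2), c(5, 7)), list(c(0, 0), c(0, 0)))
  e2 <- pooled_errors(list(c(5, 7), c(1, 2)), list(c(0, 0), c(0, 0)))
  expect_equal(sort(e1$error), sort(e2$error))
})

test_that("the range-normalised objective scales as specified", {
  expect_equal(grid_objective(list(a = rep(0, 5), b = rep(0, 5)), c(a = 1, b = 2)), 0)
  r <- 0.3
  errs <- list(x = rep(r, 10), y = rep(-r, 10), z = rep(r, 10))
  rho <- c(x = 2, y = 4, z = 5)
  expect_equal(grid_objective(errs, rho), r / 3 * sum(1 / rho))
  expect_equal(grid_objective(errs, 2 * rho),
               grid_objective(errs, rho) / 2)
  expect_error(grid_objective(errs, c(1, 0, 1)), "positive")
})

test_that("the canonical parameter grids evaluate as printed", {
  g <- default_param_grids()
  expect_equal(round(g$k_p[8], 4), 0.0046) # i = 7
  expect_equal(round(g$beta[5], 4), 0.0464)
  expect_equal(range(g$t0), c(0, 1))
  expect_equal(g$t0[13], 0.6)
  expect_equal(g$eta[1], 0.5, tolerance = 1e-12)
  expect_equal(g$eta[10], 0.01, tolerance = 1e-12)
  expect_equal(length(g$gamma), 10)
})

test_that("grid search is exhaustive, deterministic and tie-stable", {
  ds <- simulate_dataset(4, seed = 23)
  grid <- list(t0 = c(0.3, 0.6, 0.9), eta = c(0.05, 0.08))
  gs1 <- grid_search(ds, "direct_reverse", grid = grid)
  gs2 <- grid_search(ds, "direct_reverse", grid = grid)
  expect_identical(gs1$table, gs2$table)
  expect_identical(gs1$optimal, gs2$optimal)
  expect_equal(gs1$objective, min(gs1$table$objective))
  expect_equal(nrow(gs1$table), 6)
  # tie-break: with a constant objective column the first grid point wins
  fake <- gs1; fake$table$objective <- 1
  expect_equal(which.min(fake$table$objective), 1L)
})

test_that("grid search prefers accelerometer fusion under gyroscope bias", {
  beta_grid <- list(beta = c(0, 0.046, 0.22), gamma = 0.24)
  chosen <- vapply(1:20, function(seed) {
    ds <- simulate_dataset(2, seed = 3000 + seed,
                           gyro_bias = c(0.03, -0.02, 0.04))
    grid_search(ds, "madgwick", grid = beta_grid)$optimal$beta
  }, numeric(1))
  expect_gt(mean(chosen > 0), 0.5)
})

test_that("benchmarks produce finite error tables for every pipeline", {
  ds <- simulate_dataset(3, seed = 31)
  bo <- benchmark_orientation(ds)
  expect_equal(nrow(bo), 9) # 3 methods x 3 planes
  expect_true(all(is.finite(bo$accuracy_deg)) && all(is.finite(bo$precision_deg)))

  bi <- benchmark_integration(ds)
  expect_equal(nrow(bi), 12) # 3 schemes x 4 endpoints
  expect_true(all(is.finite(bi$accuracy)) && all(is.finite(bi$precision)))

  rk <- rank_methods(bi)
  expect_equal(nrow(rk), 3)
  expect_true(all(diff(rk$score) >= 0))
  expect_match(attr(rk, "criterion"), "accuracy")

  tm <- time_methods(ds[1:2, ], orient_methods = "gyro",
                     integ_methods = c("direct", "direct_reverse"))
  expect_true(all(tm$exec_ms_per_stride >= 0))
})
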