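# Benchmark harness: pooled error distributions, range-normalised grid
# search over filter parameters, and method ranking.

#' Anatomical-plane angle decomposition of an orientation track
#'
#' Intrinsic z-x-y Euler decomposition of the sensor-to-world rotation
#' (R = Rz Rx Ry): the z angle is the sagittal-plane component (pitch about
#' the transversal axis), the x angle the transversal-plane component and
#' the y angle the frontal-plane component. Angles in degrees. The
#' convention is recorded as an attribute of the result.
#'
#' @param track An `orientation_track` or any tibble/matrix with quaternion
#'   columns `qw, qx, qy, qz`.
#' @return Tibble with columns `sagittal_deg`, `transversal_deg`,
#'   `frontal_deg`.
#' @export
plane_angles <- function(track) {
  q <- track_quaternions(track)
  n <- nrow(q)
  out <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    R <- quat_to_matrix(quat_normalize(q[i, ]))
    out[i, 1] <- atan2(-R[1, 2], R[2, 2]) # z: sagittal
    out[i, 2] <- asin(max(-1, min(1, R[3, 2]))) # x: transversal
    out[i, 3] <- atan2(-R[3, 1], R[3, 3]) # y: frontal
  }
  res <- tibble::tibble(
    sagittal_deg = out[, 1] * 180 / pi,
    transversal_deg = out[, 2] * 180 / pi,
    frontal_deg = out[, 3] * 180 / pi
  )
  attr(res, "convention") <- "intrinsic z-x-y Euler angles of the sensor-to-world rotation"
  res
}

#' Pool signed per-sample errors over strides
#'
#' @param estimates,references Lists (one element per stride) of numeric
#'   vectors, or of data frames sharing the column `variable`.
#' @param variable Column to compare when data frames are given.
#' @return An `error_distribution`: tibble with `stride`, `sample` and
#'   `error` (estimate minus reference).
#' @export
pooled_errors <- function(estimates, references, variable = NULL) {
  stopifnot(length(estimates) == length(references))
  pull_var <- function(x) {
    if (is.data.frame(x)) as.numeric(x[[variable]]) else as.numeric(x)
  }
  rows <- purrr::map2(seq_along(estimates), estimates, function(i, est) {
    e <- pull_var(est) - pull_var(references[[i]])
    tibble::tibble(stride = i, sample = seq_along(e), error = e)
  })
  out <- dplyr::bind_rows(rows)
  if (!all(is.finite(out$error))) stop("pooled errors must be finite")
  structure(out, class = c("error_distribution", class(out)))
}

#' Accuracy and precision of a pooled error distribution
#'
#' Accuracy is the mean signed error, precision its standard deviation.
#'
#' @param d An `error_distribution` (or bare numeric vector of errors).
#' @return One-row tibble with `n`, `accuracy`, `precision`.
#' @export
accuracy_precision <- function(d) {
  e <- if (is.data.frame(d)) d$error else as.numeric(d)
  tibble::tibble(n = length(e), accuracy = mean(e), precision = stats::sd(e))
}

#' Range-normalised grid-search objective
#'
#' Mean over variables of the RMSE of the pooled error distribution divided
#' by the range the variable attains on the reference dataset.
#'
#' @param errors Named list of numeric error vectors, one per variable/axis.
#' @param ranges Named numeric vector of reference ranges (max - min) in the
#'   same order/names.
#' @return Non-negative scalar; 0 iff all errors are zero.
#' @export
grid_objective <- function(errors, ranges) {
  stopifnot(length(errors) == length(ranges))
  ranges <- as.numeric(ranges)
  if (any(ranges <= 0)) stop("reference ranges must be positive")
  rmse <- vapply(errors, function(e) sqrt(mean(e^2)), numeric(1))
  mean(rmse / ranges)
}

#' Parameter grids used for tuning
#'
#' The canonical grids: `beta` and `k_p` are `10^(-i/3)` for i = 0..9;
#' `gamma` is a fixed list sampling the stance-phase update coverage roughly
#' equidistantly; `k_i` is `{0, 0.01, 0.10}`; `t0` is `0.05 i` for i = 0..20;
#' `eta` is `10^(kappa - i delta)` with `kappa = log10(1/2)` and
#' `delta = (log10(1/2) + 2) / 9` for i = 0..9, spanning [0.01, 0.5].
#'
#' @return Named list of numeric parameter grids.
#' @export
default_param_grids <- function() {
  i10 <- 0:9
  kappa <- log10(1 / 2)
  delta <- (log10(1 / 2) + 2) / 9
  list(
    gamma = c(0.04, 0.07, 0.09, 0.14, 0.24, 0.45, 0.77, 1.48, 2.50, 4.00),
    beta = 10^(-i10 / 3),
    k_p = 10^(-i10 / 3),
    k_i = c(0, 0.01, 0.10),
    t0 = 0.05 * 0:20,
    eta = 10^(kappa - i10 * delta)
  )
}

reference_ranges <- function(ref_list, vars) {
  vapply(vars, function(v) {
    vals <- unlist(purrr::map(ref_list, v))
    diff(range(vals))
  }, numeric(1))
}

#' Grid search for optimal filter parameters
#'
#' Exhaustively evaluates a parameter grid on a (simulated or loaded)
#' dataset with ground-truth references and returns the configuration
#' minimising the range-normalised objective of [grid_objective()]. For the
#' orientation methods the error distributions are per-plane angle courses;
#' for direct & reverse integration they are the three velocity axes plus
#' clearance (the integration endpoints with cyclic boundary conditions).
#' Ties are broken by grid order; output is deterministic.
#'
#' @param dataset Tibble from [simulate_dataset()] (needs list-columns
#'   `recording` and `truth`).
#' @param method `"madgwick"`, `"euston"` or `"direct_reverse"`.
#' @param grid Named list of parameter vectors; defaults to the relevant
#'   subset of [default_param_grids()]. For `"euston"`, `k_i` is searched
#'   only if present in the grid.
#' @param orient_method Orientation estimator used when tuning
#'   `"direct_reverse"`. Default `"madgwick"`.
#' @return List of class `grid_search` with `optimal` (named list),
#'   `objective` (the attained minimum), `table` (tibble of all grid points
#'   and objectives) and `ranges`.
#' @export
grid_search <- function(dataset, method = c("madgwick", "euston", "direct_reverse"),
                        grid = NULL, orient_method = "madgwick") {
  method <- match.arg(method)
  grids <- default_param_grids()
  if (is.null(grid)) {
    grid <- switch(method,
      madgwick = list(beta = grids$beta, gamma = grids$gamma),
      euston = list(k_p = grids$k_p, gamma = grids$gamma),
      direct_reverse = list(t0 = grids$t0, eta = grids$eta)
    )
  }
  stopifnot(length(grid) >= 1, all(lengths(grid) >= 1))
  points <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  # expand.grid varies the first factor fastest; keep that as the tie order.

  if (method %in% c("madgwick", "euston")) {
    angle_vars <- c("sagittal_deg", "transversal_deg", "frontal_deg")
    refs <- purrr::map(dataset$truth, plane_angles)
    ranges <- reference_ranges(refs, angle_vars)
    objective <- vapply(seq_len(nrow(points)), function(r) {
      params <- if (method == "madgwick") {
        madgwick_params(beta = points$beta[r], gamma = points$gamma[r])
      } else {
        euston_params(k_p = points$k_p[r],
                      k_i = points$k_i[r] %||% 0,
                      gamma = points$gamma[r])
      }
      errs <- lapply(angle_vars, function(v) numeric(0))
      names(errs) <- angle_vars
      for (i in seq_len(nrow(dataset))) {
        est <- plane_angles(estimate_orientation(dataset$recording[[i]],
                                                 method, params))
        for (v in angle_vars) {
          errs[[v]] <- c(errs[[v]], est[[v]] - refs[[i]][[v]])
        }
      }
      grid_objective(errs, ranges)
    }, numeric(1))
  } else {
    vars <- c("vx", "vy", "vz", "sy")
    refs <- dataset$truth
    ranges <- reference_ranges(refs, vars)
    # Orientation and integrals are independent of (t0, eta): precompute.
    pre <- purrr::map(seq_len(nrow(dataset)), function(i) {
      stride <- dataset$recording[[i]]
      track <- estimate_orientation(stride, orient_method)
      sp <- stride_span(stride)
      a <- remove_gravity(to_world(track, sp$accel), time_s = sp$time)
      list(a = a, delta_t = sp$delta_t)
    })
    objective <- vapply(seq_len(nrow(points)), function(r) {
      errs <- list(vx = numeric(0), vy = numeric(0), vz = numeric(0),
                   sy = numeric(0))
      for (i in seq_len(nrow(dataset))) {
        traj <- integrate_direct_reverse(pre[[i]]$a, pre[[i]]$delta_t,
                                         t0 = points$t0[r], eta = points$eta[r])
        for (v in names(errs)) {
          errs[[v]] <- c(errs[[v]], traj[[v]] - refs[[i]][[v]])
        }
      }
      grid_objective(errs, ranges)
    }, numeric(1))
  }

  best <- which.min(objective) # first minimum: ties broken by grid order
  table <- tibble::as_tibble(points)
  table$objective <- objective
  structure(
    list(method = method, optimal = as.list(points[best, , drop = FALSE]),
         objective = objective[best], table = table, ranges = ranges),
    class = "grid_search"
  )
}

#' @export
print.grid_search <- function(x, ...) {
  cat(sprintf("<grid_search> %s over %d grid points\n", x$method, nrow(x$table)))
  cat("  optimal:", paste(names(x$optimal),
                          signif(unlist(x$optimal), 4), sep = " = ",
                          collapse = ", "),
      sprintf(" (objective %.6g)\n", x$objective))
  invisible(x)
}

#' Benchmark orientation estimators on a dataset
#'
#' Runs each estimator over all strides and pools the signed per-sample
#' plane-angle errors against the ground truth, reporting accuracy (mean),
#' precision (SD) and mean execution time per stride.
#'
#' @param dataset Tibble from [simulate_dataset()].
#' @param methods Orientation estimators to compare.
#' @param params Optional named list of parameter objects per method.
#' @return Tibble with one row per method and plane: `method`, `plane`,
#'   `accuracy_deg`, `precision_deg`, `exec_ms_per_stride`.
#' @export
benchmark_orientation <- function(dataset,
                                  methods = c("gyro", "madgwick", "euston"),
                                  params = list()) {
  angle_vars <- c("sagittal_deg", "transversal_deg", "frontal_deg")
  refs <- purrr::map(dataset$truth, plane_angles)
  purrr::map_dfr(methods, function(m) {
    t0 <- proc.time()[["elapsed"]]
    ests <- purrr::map(dataset$recording, function(rec) {
      plane_angles(estimate_orientation(rec, m, params[[m]]))
    })
    elapsed <- (proc.time()[["elapsed"]] - t0) / nrow(dataset) * 1000
    purrr::map_dfr(angle_vars, function(v) {
      d <- pooled_errors(ests, refs, variable = v)
      ap <- accuracy_precision(d)
      tibble::tibble(
        method = m, plane = sub("_deg$", "", v),
        accuracy_deg = ap$accuracy, precision_deg = ap$precision,
        exec_ms_per_stride = elapsed
      )
    })
  })
}

#' Benchmark double-integration schemes on a dataset
#'
#' Pools per-sample velocity errors (three axes) and clearance errors for
#' each integration scheme, with a fixed orientation estimator.
#'
#' @param dataset Tibble from [simulate_dataset()].
#' @param integ_methods Integration schemes to compare.
#' @param orient_method Orientation estimator used throughout. Default
#'   `"madgwick"`.
#' @param integ_params Optional named list of parameter lists per scheme.
#'   By default the analytic scheme uses 45 Fourier harmonics: at 102.4 Hz a
#'   typical stride has only ~110-140 samples, and the decomposition
#'   requires fewer harmonics than half the sample count.
#' @return Tibble with one row per method and endpoint: `method`,
#'   `endpoint` (`vx`, `vy`, `vz`, `clearance`), `accuracy`, `precision`
#'   (m/s for velocities, m for clearance), `exec_ms_per_stride`.
#' @export
benchmark_integration <- function(dataset,
                                  integ_methods = c("direct", "direct_reverse",
                                                    "analytic"),
                                  orient_method = "madgwick",
                                  integ_params = list(
                                    analytic = analytic_params(n_fourier = 45)
                                  )) {
  vars <- c(vx = "vx", vy = "vy", vz = "vz", clearance = "sy")
  purrr::map_dfr(integ_methods, function(m) {
    t0 <- proc.time()[["elapsed"]]
    ests <- purrr::map(dataset$recording, function(rec) {
      run_pipeline(rec, orient_method = orient_method, integ_method = m,
                   integ_params = integ_params[[m]])$trajectory
    })
    elapsed <- (proc.time()[["elapsed"]] - t0) / nrow(dataset) * 1000
    purrr::map_dfr(names(vars), function(nm) {
      d <- pooled_errors(ests, dataset$truth, variable = vars[[nm]])
      ap <- accuracy_precision(d)
      tibble::tibble(
        method = m, endpoint = nm,
        accuracy = ap$accuracy, precision = ap$precision,
        exec_ms_per_stride = elapsed
      )
    })
  })
}

#' Rank methods from a benchmark table
#'
#' Orders methods by a composite criterion: the mean over endpoints of
#' `(|accuracy| + precision) / 2`, smaller is better. The criterion is
#' recorded on the result.
#'
#' @param benchmark Output of [benchmark_orientation()] or
#'   [benchmark_integration()].
#' @return Tibble of methods with `score`, best first.
#' @export
rank_methods <- function(benchmark) {
  acc_col <- intersect(c("accuracy", "accuracy_deg"), names(benchmark))[1]
  prec_col <- intersect(c("precision", "precision_deg"), names(benchmark))[1]
  out <- benchmark |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(
      score = mean((abs(.data[[acc_col]]) + .data[[prec_col]]) / 2),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$score)
  attr(out, "criterion") <-
    "mean over endpoints of (|accuracy| + precision) / 2; smaller is better"
  out
}

#' Mean execution time per stride for each pipeline method
#'
#' Informational only; wall-clock timings are hardware dependent.
#'
#' @param dataset Tibble from [simulate_dataset()].
#' @param orient_methods,integ_methods Methods to time.
#' @return Tibble with `orientation`, `integration`, `exec_ms_per_stride`.
#' @export
time_methods <- function(dataset,
                         orient_methods = c("gyro", "madgwick", "euston"),
                         integ_methods = c("direct", "direct_reverse",
                                           "analytic")) {
  combos <- expand.grid(orientation = orient_methods,
                        integration = integ_methods,
                        stringsAsFactors = FALSE)
  purrr::map_dfr(seq_len(nrow(combos)), function(r) {
    t0 <- proc.time()[["elapsed"]]
    for (rec in dataset$recording) {
      run_pipeline(rec, orient_method = combos$orientation[r],
                   integ_method = combos$integration[r])
    }
    tibble::tibble(
      orientation = combos$orientation[r],
      integration = combos$integration[r],
      exec_ms_per_stride = (proc.time()[["elapsed"]] - t0) / nrow(dataset) * 1000
    )
  })
}
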