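# Per-stride orientation tracking: gyroscope integration and two
# magnetometer-free complementary filters (Madgwick; Euston/Mahony-style).

#' Madgwick complementary filter parameters
#'
#' @param beta Filter gain in rad/s, proportional to the maximal gyroscope
#'   measurement error. Default 0.046 rad/s (grid-search optimum on the
#'   reference data the methods were tuned on).
#' @param gamma Half-width of the acceptance band around 1 g within which the
#'   accelerometer magnitude must fall for an orientation update
#'   (dimensionless, in g). Default 0.24.
#' @return A list of class `madgwick_params`.
#' @export
madgwick_params <- function(beta = 0.046, gamma = 0.24) {
  stopifnot(is.finite(beta), beta >= 0, !is.na(gamma), gamma >= 0)
  structure(list(beta = beta, gamma = gamma), class = "madgwick_params")
}

#' Euston complementary filter parameters
#'
#' @param k_p Proportional gain in rad/s. Default 0.0046.
#' @param k_i Integral gain in rad/s, corrects constant gyroscope bias.
#'   Default 0 (suitable for per-stride integration times).
#' @param gamma Accelerometer acceptance band half-width in g. Default 2.50.
#' @return A list of class `euston_params`.
#' @export
euston_params <- function(k_p = 0.0046, k_i = 0, gamma = 2.50) {
  stopifnot(is.finite(k_p), k_p >= 0, is.finite(k_i), k_i >= 0,
            !is.na(gamma), gamma >= 0)
  structure(list(k_p = k_p, k_i = k_i, gamma = gamma), class = "euston_params")
}

#' Maximal gyroscope error implied by a Madgwick gain
#'
#' Two published relations link the gain `beta` to the maximal gyroscope
#' measurement error it compensates: Madgwick's original
#' `beta = sqrt(3/4) * omega_max` (so `omega_max = 2/sqrt(3) * beta`), and
#' the simpler proportionality `omega_max = 4/3 * beta`.
#'
#' @param beta Gain in rad/s.
#' @param relation `"madgwick"` (default) or `"four_thirds"`.
#' @return Maximal gyroscope error in degrees per second.
#' @export
madgwick_max_gyro_error <- function(beta, relation = c("madgwick", "four_thirds")) {
  relation <- match.arg(relation)
  omega_max <- switch(relation,
    madgwick = beta * 2 / sqrt(3),
    four_thirds = beta * 4 / 3
  )
  omega_max * 180 / pi
}

#' Gate accelerometer orientation updates
#'
#' An accelerometer sample may correct the orientation only when the foot is
#' not in swing and the measured magnitude is within `gamma` of 1 g, i.e.
#' the reading is dominated by gravity.
#'
#' @param accel Length-3 accelerometer sample in g.
#' @param gamma Acceptance band half-width in g.
#' @param in_swing Logical: is the sample inside the swing phase?
#' @return Logical flag: apply the accelerometer update?
#' @export
accel_gate <- function(accel, gamma, in_swing = FALSE) {
  if (isTRUE(in_swing)) return(FALSE)
  abs(sqrt(sum(accel^2)) - 1) <= gamma
}

#' Detect the swing phase from gyroscope energy
#'
#' Swing is marked where the angular rate norm exceeds `threshold`;
#' morphological closing over `close_s` seconds fills short sub-threshold
#' gaps inside the swing. Stance is the complement.
#'
#' @param gyro n x 3 matrix of angular rates in rad/s.
#' @param delta_t Sampling interval in s.
#' @param threshold Angular-rate norm threshold in rad/s. Default 1.5.
#' @param close_s Closing window in seconds. Default 0.05.
#' @return Logical vector, TRUE during swing.
#' @export
detect_swing <- function(gyro, delta_t, threshold = 1.5, close_s = 0.05) {
  gyro <- as_vec3_matrix(gyro, c("gx", "gy", "gz"))
  swing <- sqrt(rowSums(gyro^2)) > threshold
  gap <- max(1L, as.integer(round(close_s / delta_t)))
  close_gaps(swing, gap)
}

# Morphological closing of a logical vector: set FALSE runs shorter than
# `gap` samples to TRUE when flanked by TRUE on both sides.
close_gaps <- function(x, gap) {
  r <- rle(x)
  n_runs <- length(r$values)
  if (n_runs > 2) {
    for (k in seq(2, n_runs - 1)) {
      if (!r$values[k] && r$lengths[k] < gap) r$values[k] <- TRUE
    }
  }
  inverse.rle(r)
}

# Predicted specific-force direction in the sensor frame: R(q)^T (0, 1, 0).
# Its negative is gravity transformed to sensor coordinates, R(q)^T g_w.
predict_specific_force <- function(q) {
  c(
    2 * (q[2] * q[3] + q[1] * q[4]),
    q[1]^2 - q[2]^2 + q[3]^2 - q[4]^2,
    2 * (q[3] * q[4] - q[1] * q[2])
  )
}

# Jacobian of predict_specific_force with respect to (q0, q1, q2, q3).
specific_force_jacobian <- function(q) {
  q0 <- q[1]; q1 <- q[2]; q2 <- q[3]; q3 <- q[4]
  matrix(c(
     2 * q3,  2 * q2,  2 * q1,  2 * q0,
     2 * q0, -2 * q1,  2 * q2, -2 * q3,
    -2 * q1, -2 * q0,  2 * q3,  2 * q2
  ), nrow = 3, byrow = TRUE)
}

#' One Madgwick filter step
#'
#' Gradient-descent correction of the gyroscope-propagated quaternion toward
#' the orientation whose predicted gravity direction matches the
#' accelerometer reading. With `use_accel = FALSE` (or `beta = 0`) the step
#' reduces exactly to first-order gyroscope integration. When the error
#' gradient vanishes the step falls back to the pure gyroscope update.
#'
#' @param q_prev Unit quaternion at the previous sample.
#' @param omega Angular rate, rad/s, sensor frame.
#' @param accel Accelerometer sample in g, sensor frame.
#' @param params A [madgwick_params()].
#' @param use_accel Logical gate from [accel_gate()].
#' @param delta_t Sampling interval in s.
#' @return Unit quaternion at the current sample.
#' @export
madgwick_step <- function(q_prev, omega, accel, params, use_accel, delta_t) {
  qdot <- quat_derivative(q_prev, omega)
  if (isTRUE(use_accel) && params$beta > 0) {
    eps <- predict_specific_force(q_prev) - accel
    grad <- as.numeric(crossprod(specific_force_jacobian(q_prev), eps))
    gnorm <- sqrt(sum(grad^2))
    if (gnorm > 0) qdot <- qdot - params$beta * grad / gnorm
  }
  quat_normalize(q_prev + qdot * delta_t)
}

#' One Euston filter step
#'
#' Explicit complementary filter: the angular mismatch between the predicted
#' and measured gravity direction (their cross product) is fed back onto the
#' measured angular rate with proportional and integral gains before the
#' quaternion update. With `k_p = k_i = 0` the step reduces exactly to
#' gyroscope integration; a zero-norm accelerometer sample disables the
#' update.
#'
#' @param q_prev Unit quaternion at the previous sample.
#' @param omega Angular rate, rad/s.
#' @param accel Accelerometer sample in g.
#' @param params An [euston_params()].
#' @param use_accel Logical gate from [accel_gate()].
#' @param integ_state Filter state: list with `integral` (accumulated error
#'   integral, length 3) and `e_prev` (previous error, length 3), both reset
#'   to zero at each stride start.
#' @param delta_t Sampling interval in s.
#' @return List with `q` (updated unit quaternion) and `integ_state`.
#' @export
euston_step <- function(q_prev, omega, accel, params, use_accel, integ_state,
                        delta_t) {
  e <- c(0, 0, 0)
  anorm <- sqrt(sum(accel^2))
  if (isTRUE(use_accel) && anorm > 0) {
    gs <- -predict_specific_force(q_prev) # gravity direction in sensor frame
    gs <- gs / sqrt(sum(gs^2))
    ahat <- accel / anorm
    e <- c(
      gs[2] * ahat[3] - gs[3] * ahat[2],
      gs[3] * ahat[1] - gs[1] * ahat[3],
      gs[1] * ahat[2] - gs[2] * ahat[1]
    )
  }
  integral <- integ_state$integral + (integ_state$e_prev + e) / 2 * delta_t
  delta <- params$k_p * e + params$k_i * integral
  qdot <- quat_derivative(q_prev, omega + delta)
  list(
    q = quat_normalize(q_prev + qdot * delta_t),
    integ_state = list(integral = integral, e_prev = e)
  )
}

#' Track foot orientation over one stride
#'
#' Propagates the sensor-to-world quaternion from the first to the second
#' mid-stance with one of three estimators: first-order gyroscope
#' integration (`"gyro"`), the gated, magnetometer-free Madgwick
#' complementary filter (`"madgwick"`) or the Euston/Mahony explicit
#' complementary filter (`"euston"`). The initial quaternion comes from
#' [initial_orientation()] at the first mid-stance.
#'
#' @param stride A [stride_recording()].
#' @param method One of `"gyro"`, `"madgwick"`, `"euston"`.
#' @param params A [madgwick_params()] or [euston_params()] matching
#'   `method`; ignored for `"gyro"`. Defaults to the method's defaults.
#' @param swing Optional logical vector over the stride span marking the
#'   swing phase (accelerometer updates are suppressed there); computed with
#'   [detect_swing()] when missing.
#' @param swing_threshold,swing_close_s Passed to [detect_swing()].
#' @return An orientation track: tibble with columns `time_s`,
#'   `qw, qx, qy, qz` (unit quaternions, sensor-to-world) and `accel_update`
#'   (was an accelerometer correction applied at this sample?), with class
#'   `orientation_track`.
#' @export
estimate_orientation <- function(stride, method = c("gyro", "madgwick", "euston"),
                                 params = NULL, swing = NULL,
                                 swing_threshold = 1.5, swing_close_s = 0.05) {
  method <- match.arg(method)
  sp <- stride_span(stride)
  n <- length(sp$idx)
  if (is.null(params)) {
    params <- switch(method,
      gyro = NULL,
      madgwick = madgwick_params(),
      euston = euston_params()
    )
  }
  if (is.null(swing)) {
    swing <- detect_swing(sp$gyro, sp$delta_t, swing_threshold, swing_close_s)
  }
  stopifnot(length(swing) == n)

  q <- matrix(NA_real_, n, 4)
  mask <- logical(n)
  q[1, ] <- initial_orientation(sp$accel[1, ])
  state <- list(integral = c(0, 0, 0), e_prev = c(0, 0, 0))
  gamma <- if (method == "gyro") 0 else params$gamma
  for (i in seq_len(n)[-1]) {
    omega <- sp$gyro[i, ]
    accel <- sp$accel[i, ]
    use_accel <- if (method == "gyro") FALSE else accel_gate(accel, gamma, swing[i])
    q_prev <- q[i - 1, ]
    q[i, ] <- switch(method,
      gyro = quat_normalize(q_prev + quat_derivative(q_prev, omega) * sp$delta_t),
      madgwick = madgwick_step(q_prev, omega, accel, params, use_accel, sp$delta_t),
      euston = {
        st <- euston_step(q_prev, omega, accel, params, use_accel, state, sp$delta_t)
        state <- st$integ_state
        st$q
      }
    )
    mask[i] <- use_accel
  }
  out <- tibble::tibble(
    time_s = sp$time, qw = q[, 1], qx = q[, 2], qy = q[, 3], qz = q[, 4],
    accel_update = mask
  )
  structure(out,
    class = c("orientation_track", class(out)),
    method = method, params = params, swing = swing, delta_t = sp$delta_t
  )
}

#' Fraction of the stance phase receiving an accelerometer update
#'
#' @param track An `orientation_track` from [estimate_orientation()].
#' @param stance_mask Logical vector, TRUE during stance; defaults to the
#'   complement of the swing mask stored on the track.
#' @return Fraction in `[0, 1]` (NA when there are no stance samples).
#' @export
stance_update_fraction <- function(track, stance_mask = NULL) {
  if (is.null(stance_mask)) stance_mask <- !attr(track, "swing")
  stopifnot(length(stance_mask) == nrow(track))
  # the first sample is the initialisation, not an update step
  keep <- stance_mask & (seq_along(stance_mask) > 1)
  if (!any(keep)) return(NA_real_)
  sum(track$accel_update[keep]) / sum(keep)
}

# n x 4 quaternion matrix from an orientation track or tibble.
track_quaternions <- function(track) {
  as.matrix(as.data.frame(track)[, c("qw", "qx", "qy", "qz")])
}
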