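# World-frame transformation, gravity removal with dedrifting, and the
# numeric double-integration schemes (direct; direct & time-reversed fusion).

#' Rotate sensor-frame accelerations into the world frame
#'
#' @param track An `orientation_track` (or tibble with `qw..qz`) covering the
#'   stride span.
#' @param accel_sensor n x 3 matrix (or data frame with `ax, ay, az`) of
#'   accelerometer samples in g over the same span.
#' @return Tibble with columns `awx, awy, awz`: accelerations in the world
#'   frame, still in g.
#' @export
to_world <- function(track, accel_sensor) {
  q <- track_quaternions(track)
  a <- as_vec3_matrix(accel_sensor, c("ax", "ay", "az"))
  stopifnot(nrow(q) == nrow(a))
  out <- matrix(NA_real_, nrow(a), 3)
  for (i in seq_len(nrow(a))) {
    out[i, ] <- quat_to_matrix(q[i, ]) %*% a[i, ]
  }
  tibble::tibble(awx = out[, 1], awy = out[, 2], awz = out[, 3])
}

#' Remove gravity and enforce the zero-acceleration boundary condition
#'
#' Subtracts the specific force of gravity (0, 1, 0) g from world-frame
#' accelerations, converts to m/s^2, and dedrifts each axis with a piecewise
#' linear function so the movement acceleration is exactly zero at both
#' mid-stances. The piecewise correction uses two linear segments per axis,
#' joined with value zero at the sample of maximal acceleration norm, so the
#' high-movement part of the stride is left untouched; `dedrift = "linear"`
#' falls back to a single interpolating line, `"none"` disables it.
#'
#' @param aw n x 3 matrix or tibble (`awx, awy, awz`) of world-frame
#'   accelerations in g.
#' @param frame A [world_frame()].
#' @param dedrift `"piecewise"` (default), `"linear"` or `"none"`.
#' @param time_s Optional time stamps carried through to the result.
#' @return A `world_accel_track`: tibble with `time_s` (if given) and
#'   `ax_w, ay_w, az_w` in m/s^2, first and last rows exactly zero (unless
#'   `dedrift = "none"`).
#' @export
remove_gravity <- function(aw, frame = world_frame(),
                           dedrift = c("piecewise", "linear", "none"),
                           time_s = NULL) {
  dedrift <- match.arg(dedrift)
  aw <- as_vec3_matrix(aw, c("awx", "awy", "awz"))
  n <- nrow(aw)
  if (n < 3) stop("need at least 3 samples to remove gravity and dedrift")
  a <- (aw - matrix(c(0, 1, 0), n, 3, byrow = TRUE)) * frame$g_mag
  if (dedrift != "none") {
    joint <- which.max(rowSums(a^2))
    for (ax in 1:3) {
      a[, ax] <- a[, ax] - drift_correction(a[, ax], n, joint, dedrift)
    }
  }
  out <- tibble::tibble(ax_w = a[, 1], ay_w = a[, 2], az_w = a[, 3])
  if (!is.null(time_s)) out <- tibble::add_column(out, time_s = time_s, .before = 1)
  structure(out, class = c("world_accel_track", class(out)), g_mag = frame$g_mag)
}

# Piecewise-linear (or single-line) drift function through the endpoint
# residuals: equals x[1] at the first sample and x[n] at the last; the
# piecewise variant is zero at the joint sample.
drift_correction <- function(x, n, joint, kind) {
  idx <- seq_len(n)
  if (kind == "linear" || joint <= 1 || joint >= n) {
    return(x[1] + (x[n] - x[1]) * ((idx - 1) / (n - 1)))
  }
  d <- numeric(n)
  d[1:joint] <- x[1] * ((joint - idx[1:joint]) / (joint - 1))
  d[joint:n] <- x[n] * ((idx[joint:n] - joint) / (n - joint))
  d
}

#' Cumulative integral by the trapezoidal rule
#'
#' @param x Numeric sequence (length >= 2).
#' @param delta_t Sampling interval in s.
#' @return Sequence of the same length, starting exactly at 0.
#' @export
trapezoid_cumint <- function(x, delta_t) {
  n <- length(x)
  stopifnot(n >= 2, delta_t > 0)
  c(0, cumsum((x[-1] + x[-n]) / 2 * delta_t))
}

#' Subtract the linear drift fixed by the endpoint values
#'
#' Removes the straight line through the first and last samples so both
#' endpoints become exactly zero; the standard correction enforcing the
#' zero-velocity (or level-floor) boundary condition after integration.
#'
#' @param y Numeric sequence (length >= 2).
#' @return Dedrifted sequence with `y[1] == y[n] == 0` exactly.
#' @export
linear_dedrift <- function(y) {
  n <- length(y)
  stopifnot(n >= 2)
  # evaluate the fraction first so the endpoints cancel exactly in floating point
  frac <- (seq_len(n) - 1) / (n - 1)
  y - (y[1] + (y[n] - y[1]) * frac)
}

#' Flip an acceleration signal in time and direction
#'
#' @param a n x 3 matrix (or vector) of accelerations.
#' @return The reversed signal `-a[n:1, ]`; applying it twice restores the
#'   input.
#' @export
reverse_accel <- function(a) {
  if (is.null(dim(a))) return(-rev(a))
  -a[rev(seq_len(nrow(a))), , drop = FALSE]
}

#' Sigmoid fusion weights for direct & reverse integration
#'
#' Logistic curve `h(t) = 1 / (1 + exp(-(t - t0) / eta))` on normalised
#' stride time, shifted and scaled by its endpoint values so that
#' `w[1] == 0` and `w[n] == 1` exactly.
#'
#' @param n Number of samples in the stride.
#' @param t0 Sigmoid midpoint as a fraction of stride duration, in `[0, 1]`.
#'   Default 0.6.
#' @param eta Steepness (> 0); large values approach a linear ramp.
#'   Default 0.08.
#' @return Monotone non-decreasing weight sequence in `[0, 1]`.
#' @export
sigmoid_weight <- function(n, t0 = 0.6, eta = 0.08) {
  stopifnot(n >= 2, eta > 0, t0 >= 0, t0 <= 1)
  tau <- (seq_len(n) - 1) / (n - 1)
  h <- 1 / (1 + exp(-(tau - t0) / eta))
  (h - h[1]) / (h[n] - h[1])
}

# Fused direct / time-reversed cumulative integral of one axis. The forward
# integral starts exactly at 0; the reversed integral is anchored so the
# final value is exactly 0; the sigmoid weights select between them.
fuse_direct_reverse <- function(x, delta_t, w) {
  fwd <- trapezoid_cumint(x, delta_t)
  rev_star <- trapezoid_cumint(-rev(x), delta_t)
  bwd <- rev(rev_star)
  (1 - w) * fwd + w * bwd
}

new_trajectory <- function(time_s, v, s, method, delta_t) {
  out <- tibble::tibble(
    time_s = time_s,
    vx = v[, 1], vy = v[, 2], vz = v[, 3],
    sx = s[, 1], sy = s[, 2], sz = s[, 3]
  )
  structure(out, class = c("trajectory_estimate", class(out)),
            method = method, delta_t = delta_t)
}

#' Direct double integration with linear dedrifting
#'
#' Velocity is the trapezoidal integral of the movement acceleration,
#' linearly dedrifted per axis to honour the zero-velocity assumption;
#' position is the trapezoidal integral of velocity, with the vertical axis
#' linearly dedrifted once more to honour the level-floor assumption.
#'
#' @param a A `world_accel_track` from [remove_gravity()].
#' @param delta_t Sampling interval in s.
#' @param time_s Optional timestamps (taken from `a` when present).
#' @return A `trajectory_estimate`: tibble with `time_s`, `vx, vy, vz` (m/s)
#'   and `sx, sy, sz` (m).
#' @export
integrate_direct <- function(a, delta_t, time_s = NULL) {
  am <- accel_matrix(a)
  time_s <- traj_time(a, time_s, nrow(am), delta_t)
  v <- apply(am, 2, function(x) linear_dedrift(trapezoid_cumint(x, delta_t)))
  s <- apply(v, 2, trapezoid_cumint, delta_t = delta_t)
  s[, 2] <- linear_dedrift(s[, 2])
  new_trajectory(time_s, v, s, "direct", delta_t)
}

#' Direct & time-reversed double integration with sigmoid fusion
#'
#' Computes the forward integral and the integral of the time- and
#' direction-flipped signal (re-indexed back onto forward time), and fuses
#' them with a sigmoid weight so the known initial value anchors the start
#' and the known final value anchors the end of each integral — without any
#' explicit dedrifting. Applied to velocity on all axes and again to the
#' vertical position, whose boundary values are also known a priori
#' (level floor). Ground-plane position is obtained by direct integration of
#' the fused velocity.
#'
#' @param a A `world_accel_track` from [remove_gravity()].
#' @param delta_t Sampling interval in s.
#' @param t0,eta Sigmoid parameters, see [sigmoid_weight()].
#' @param time_s Optional timestamps.
#' @return A `trajectory_estimate`.
#' @export
integrate_direct_reverse <- function(a, delta_t, t0 = 0.6, eta = 0.08,
                                     time_s = NULL) {
  am <- accel_matrix(a)
  n <- nrow(am)
  time_s <- traj_time(a, time_s, n, delta_t)
  w <- sigmoid_weight(n, t0, eta)
  v <- apply(am, 2, fuse_direct_reverse, delta_t = delta_t, w = w)
  s <- apply(v, 2, trapezoid_cumint, delta_t = delta_t)
  s[, 2] <- fuse_direct_reverse(v[, 2], delta_t, w)
  new_trajectory(time_s, v, s, "direct_reverse", delta_t)
}

accel_matrix <- function(a) {
  as_vec3_matrix(a, c("ax_w", "ay_w", "az_w"))
}

traj_time <- function(a, time_s, n, delta_t) {
  if (!is.null(time_s)) return(time_s)
  if (is.data.frame(a) && "time_s" %in% names(a)) return(a$time_s)
  (seq_len(n) - 1) * delta_t
}
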