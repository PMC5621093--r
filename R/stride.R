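# Per-stride data model, mid-stance detection and initial inclination.

#' Construct a per-stride IMU recording
#'
#' A stride recording bundles synchronized gyroscope and accelerometer time
#' series (sensor frame) with the two mid-stance anchors that define the
#' stride. Gyroscope rates are in rad/s, accelerations in units of g, and
#' timestamps must be uniformly sampled.
#'
#' @param data Data frame with columns `time_s`, `gx`, `gy`, `gz` (rad/s) and
#'   `ax`, `ay`, `az` (g).
#' @param i_ms_start,i_ms_end 1-based sample indices of two consecutive
#'   mid-stances. The stride used for integration spans
#'   `[i_ms_start, i_ms_end]`. Defaults: first and last sample.
#' @param delta_t Sampling interval in seconds; inferred from `time_s` when
#'   missing. Default sampling rate is 102.4 Hz.
#' @return An object of class `stride_recording`: a list with the data tibble
#'   and the stride anchors.
#' @export
stride_recording <- function(data, i_ms_start = 1L, i_ms_end = nrow(data),
                             delta_t = NULL) {
  required <- c("time_s", "gx", "gy", "gz", "ax", "ay", "az")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    stop("stride data is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  data <- tibble::as_tibble(data)[required]
  if (nrow(data) < 4) stop("a stride recording needs at least 4 samples")
  if (!all(is.finite(as.matrix(data)))) stop("stride data must be finite")
  dt_obs <- diff(data$time_s)
  if (any(dt_obs <= 0)) stop("timestamps must be strictly increasing")
  if (is.null(delta_t)) delta_t <- stats::median(dt_obs)
  if (delta_t <= 0) stop("delta_t must be positive")
  if (max(abs(dt_obs - delta_t)) > 1e-6) {
    stop("timestamps must be uniformly sampled (within 1e-6 s of delta_t)")
  }
  i_ms_start <- as.integer(i_ms_start)
  i_ms_end <- as.integer(i_ms_end)
  if (!(i_ms_start >= 1 && i_ms_end <= nrow(data) && i_ms_start < i_ms_end)) {
    stop("mid-stance anchors must satisfy 1 <= i_ms_start < i_ms_end <= n")
  }
  if (i_ms_end - i_ms_start < 3) {
    stop("at least 3 samples are required between the mid-stance anchors")
  }
  structure(
    list(data = data, i_ms_start = i_ms_start, i_ms_end = i_ms_end,
         delta_t = delta_t),
    class = "stride_recording"
  )
}

#' @export
print.stride_recording <- function(x, ...) {
  cat(sprintf(
    "<stride_recording> %d samples @ %.6f s (%.1f Hz), mid-stances at %d and %d (T = %.3f s)\n",
    nrow(x$data), x$delta_t, 1 / x$delta_t, x$i_ms_start, x$i_ms_end,
    (x$i_ms_end - x$i_ms_start) * x$delta_t
  ))
  print(x$data, n = 3)
  invisible(x)
}

#' World frame convention
#'
#' The world frame has gravity along -y; at rest an ideal accelerometer
#' therefore reads the specific force (0, 1, 0) in units of g.
#'
#' @param g_mag Gravity magnitude in m/s^2 used to convert accelerations from
#'   g to SI units. Default 9.81.
#' @return A list with `gravity_world` (unit direction) and `g_mag`.
#' @export
world_frame <- function(g_mag = 9.81) {
  stopifnot(is.numeric(g_mag), g_mag > 0)
  list(gravity_world = c(0, -1, 0), g_mag = g_mag)
}

#' Detect mid-stance as the minimal-energy instant of the gyroscope signal
#'
#' Slides a window over the squared gyroscope norm and returns the centre
#' index of the window with minimal summed energy; ties are broken by the
#' earliest index.
#'
#' @param gyro Numeric n x 3 matrix (or data frame with columns gx, gy, gz)
#'   of angular rates in rad/s.
#' @param window Window length in samples (>= 1). The default 0.1 s at
#'   102.4 Hz is robust against single-sample noise while staying inside the
#'   stance plateau.
#' @return 1-based index of the detected mid-stance sample.
#' @export
detect_midstance <- function(gyro, window = 10L) {
  gyro <- as_vec3_matrix(gyro, c("gx", "gy", "gz"))
  n <- nrow(gyro)
  if (n == 0) stop("empty gyroscope sequence")
  window <- as.integer(window)
  if (window < 1 || window > n) stop("window must be in [1, nrow(gyro)]")
  energy <- rowSums(gyro^2)
  win_sum <- as.numeric(stats::filter(energy, rep(1, window), sides = 1))
  # win_sum[i] covers samples (i - window + 1):i; centre of that window:
  starts <- seq_len(n - window + 1)
  sums <- win_sum[starts + window - 1L]
  best <- which.min(sums) # which.min takes the first minimum: earliest tie-break
  starts[best] + (window - 1L) %/% 2L
}

#' Initial inclination from the accelerometer at mid-stance
#'
#' At mid-stance the accelerometer is assumed to measure pure gravity, so the
#' sensor tilt about the transversal (z) and anterior-posterior (x) axes can
#' be recovered; heading about the vertical is unobservable and left at zero.
#' The tilt angles are `alpha_z = atan2(-ax, ay)` and
#' `alpha_x = atan2(az, sqrt(ax^2 + ay^2))`, and the returned sensor-to-world
#' quaternion maps the measured specific force onto world +y.
#'
#' @param accel_at_ms Numeric length-3 accelerometer sample (units of g) at
#'   mid-stance.
#' @return Unit quaternion (sensor-to-world) with zero heading component.
#' @export
initial_orientation <- function(accel_at_ms) {
  a <- as.numeric(accel_at_ms)
  stopifnot(length(a) == 3)
  if (sqrt(sum(a^2)) == 0) stop("zero-norm accelerometer sample at mid-stance")
  alpha_z <- atan2(-a[1], a[2])
  alpha_x <- atan2(a[3], sqrt(a[1]^2 + a[2]^2))
  qz <- quat_from_axis_angle(c(0, 0, 1), alpha_z)
  qx <- quat_from_axis_angle(c(1, 0, 0), alpha_x)
  # Measured gravity direction decomposes as a_s = Rz(alpha_z) Rx(alpha_x) (0,1,0);
  # the sensor-to-world rotation is the inverse of that tilt.
  quat_conjugate(quat_multiply(qz, qx))
}

#' Read one stride from CSV
#'
#' Expects the stride CSV dialect: comma-separated, header row, '.' decimal,
#' columns `time_s, gx, gy, gz, ax, ay, az` (rad/s and g). Mid-stance anchors
#' can be supplied directly or read from an events CSV with columns
#' `i_ms_start, i_ms_end`.
#'
#' @param file Path to the stride CSV.
#' @param events Optional path to an events CSV, or a list/row with
#'   `i_ms_start` and `i_ms_end`.
#' @return A [stride_recording()].
#' @export
read_stride_csv <- function(file, events = NULL) {
  data <- readr::read_csv(file, show_col_types = FALSE, progress = FALSE)
  i0 <- 1L
  i1 <- nrow(data)
  if (!is.null(events)) {
    ev <- if (is.character(events)) {
      readr::read_csv(events, show_col_types = FALSE, progress = FALSE)
    } else {
      events
    }
    i0 <- as.integer(ev$i_ms_start[1])
    i1 <- as.integer(ev$i_ms_end[1])
  }
  stride_recording(data, i_ms_start = i0, i_ms_end = i1)
}

#' Write a stride recording (and its events) to CSV
#'
#' @param stride A [stride_recording()].
#' @param file Output path for the signal CSV.
#' @param events_file Optional output path for the events CSV
#'   (`i_ms_start, i_ms_end`).
#' @return `file`, invisibly.
#' @export
write_stride_csv <- function(stride, file, events_file = NULL) {
  readr::write_csv(stride$data, file)
  if (!is.null(events_file)) {
    readr::write_csv(
      tibble::tibble(i_ms_start = stride$i_ms_start, i_ms_end = stride$i_ms_end),
      events_file
    )
  }
  invisible(file)
}

# Coerce a data frame / matrix to an n x 3 numeric matrix.
as_vec3_matrix <- function(x, cols = NULL) {
  if (is.data.frame(x)) {
    if (!is.null(cols) && all(cols %in% names(x))) x <- x[cols]
    x <- as.matrix(x)
  }
  if (is.null(dim(x))) x <- matrix(x, ncol = 3, byrow = TRUE)
  storage.mode(x) <- "double"
  stopifnot(ncol(x) == 3)
  x
}

# Gyro/accel matrices over the stride span [i_ms_start, i_ms_end].
stride_span <- function(stride) {
  idx <- stride$i_ms_start:stride$i_ms_end
  list(
    idx = idx,
    time = stride$data$time_s[idx],
    gyro = as.matrix(stride$data[idx, c("gx", "gy", "gz")]),
    accel = as.matrix(stride$data[idx, c("ax", "ay", "az")]),
    delta_t = stride$delta_t
  )
}
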