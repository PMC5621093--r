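# Full per-stride processing pipeline: orientation estimation, coordinate
# transform, gravity removal and double integration.

#' Estimate the foot trajectory of one stride
#'
#' Runs the complete stride-wise pipeline: initial inclination at the first
#' mid-stance, orientation tracking, rotation of the accelerations into the
#' world frame, gravity removal with piecewise-linear dedrifting, and double
#' integration under the zero-velocity and level-floor boundary conditions.
#' Any of the 3 x 3 method combinations can be selected; the pipeline is
#' deterministic.
#'
#' @param stride A [stride_recording()].
#' @param orient_method `"gyro"`, `"madgwick"` or `"euston"`.
#' @param orient_params Optional [madgwick_params()] / [euston_params()].
#' @param integ_method `"direct"`, `"direct_reverse"` or `"analytic"`.
#' @param integ_params For `"direct_reverse"`: a list with `t0` and `eta`;
#'   for `"analytic"`: an [analytic_params()]. Defaults per method.
#' @param frame A [world_frame()].
#' @param dedrift Acceleration dedrifting variant, see [remove_gravity()].
#' @param swing_threshold,swing_close_s Swing-phase detection settings, see
#'   [detect_swing()].
#' @return An object of class `foot_trajectory` with elements `orientation`
#'   (the `orientation_track`), `trajectory` (the `trajectory_estimate`),
#'   `accel_world` (dedrifted movement acceleration), `summary` (one-row
#'   tibble: stride length, stride duration, maximal clearance) and the
#'   methods/parameters used.
#' @examples
#' stride <- simulate_stride(synthetic_stride_spec(seed = 1))$recording
#' fit <- run_pipeline(stride)
#' fit$summary
#' @export
run_pipeline <- function(stride,
                         orient_method = c("madgwick", "gyro", "euston"),
                         orient_params = NULL,
                         integ_method = c("direct_reverse", "direct", "analytic"),
                         integ_params = NULL,
                         frame = world_frame(),
                         dedrift = "piecewise",
                         swing_threshold = 1.5, swing_close_s = 0.05) {
  orient_method <- match.arg(orient_method)
  integ_method <- match.arg(integ_method)
  track <- estimate_orientation(stride, orient_method, orient_params,
                                swing_threshold = swing_threshold,
                                swing_close_s = swing_close_s)
  sp <- stride_span(stride)
  aw <- to_world(track, sp$accel)
  a <- remove_gravity(aw, frame, dedrift = dedrift, time_s = sp$time)
  traj <- switch(integ_method,
    direct = integrate_direct(a, sp$delta_t),
    direct_reverse = {
      p <- integ_params %||% list()
      integrate_direct_reverse(a, sp$delta_t,
                               t0 = p$t0 %||% 0.6, eta = p$eta %||% 0.08)
    },
    analytic = integrate_analytic(a, sp$delta_t,
                                  params = integ_params %||% analytic_params())
  )
  n <- nrow(traj)
  summary <- tibble::tibble(
    stride_length_m = sqrt(traj$sx[n]^2 + traj$sz[n]^2),
    stride_duration_s = (sp$idx[length(sp$idx)] - sp$idx[1]) * sp$delta_t,
    max_clearance_m = max(traj$sy)
  )
  structure(
    list(orientation = track, trajectory = traj, accel_world = a,
         summary = summary,
         methods = list(orientation = orient_method, integration = integ_method),
         params = list(orientation = attr(track, "params"),
                       integration = integ_params)),
    class = "foot_trajectory"
  )
}

#' @export
print.foot_trajectory <- function(x, ...) {
  cat(sprintf(
    "<foot_trajectory> %s orientation + %s integration\n",
    x$methods$orientation, x$methods$integration
  ))
  cat(sprintf(
    "  stride length %.3f m, duration %.3f s, max clearance %.3f m\n",
    x$summary$stride_length_m, x$summary$stride_duration_s,
    x$summary$max_clearance_m
  ))
  invisible(x)
}

#' Write a per-stride trajectory estimate to CSV
#'
#' Columns `time_s, vx, vy, vz, sx, sy, sz`; scalar summaries and run
#' metadata (methods, parameters, package version) go to a JSON side-car.
#'
#' @param fit A `foot_trajectory` from [run_pipeline()].
#' @param file Output CSV path.
#' @param meta_file Optional JSON metadata path.
#' @return `file`, invisibly.
#' @export
write_trajectory_csv <- function(fit, file, meta_file = NULL) {
  readr::write_csv(tibble::as_tibble(fit$trajectory), file)
  if (!is.null(meta_file)) {
    meta <- list(
      methods = fit$methods,
      params = lapply(fit$params, function(p) {
        if (is.null(p)) NULL else unclass(p)
      }),
      summary = as.list(fit$summary),
      package = "gaittraj",
      version = as.character(utils::packageVersion("gaittraj"))
    )
    jsonlite::write_json(meta, meta_file, auto_unbox = TRUE, digits = NA,
                         null = "null")
  }
  invisible(file)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
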