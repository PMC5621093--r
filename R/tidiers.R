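# broom-style tidiers for fitted pipeline objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted foot trajectory
#'
#' One row per sample and variable, in long form.
#'
#' @param x A `foot_trajectory` from [run_pipeline()].
#' @param ... Unused.
#' @return Tibble with `time_s`, `variable` (`vx..vz`, `sx..sz`) and `value`.
#' @export
tidy.foot_trajectory <- function(x, ...) {
  tibble::as_tibble(x$trajectory) |>
    tidyr::pivot_longer(-"time_s", names_to = "variable", values_to = "value")
}

#' One-row summary of a fitted foot trajectory
#'
#' @param x A `foot_trajectory`.
#' @param ... Unused.
#' @return One-row tibble: methods, stride length (m), duration (s), maximal
#'   clearance (m) and the stance-phase accelerometer-update fraction.
#' @export
glance.foot_trajectory <- function(x, ...) {
  tibble::tibble(
    orient_method = x$methods$orientation,
    integ_method = x$methods$integration,
    stride_length_m = x$summary$stride_length_m,
    stride_duration_s = x$summary$stride_duration_s,
    max_clearance_m = x$summary$max_clearance_m,
    stance_update_fraction = stance_update_fraction(x$orientation)
  )
}

#' Tidy an orientation track
#'
#' @param x An `orientation_track` from [estimate_orientation()].
#' @param ... Unused.
#' @return Tibble with `time_s`, the plane angles in degrees (long form) and
#'   the accelerometer-update flag.
#' @export
tidy.orientation_track <- function(x, ...) {
  ang <- plane_angles(x)
  dplyr::bind_cols(tibble::tibble(time_s = x$time_s), ang,
                   tibble::tibble(accel_update = x$accel_update)) |>
    tidyr::pivot_longer(dplyr::ends_with("_deg"),
                        names_to = "plane", values_to = "angle_deg") |>
    dplyr::mutate(plane = sub("_deg$", "", .data$plane))
}

#' Tidy a grid search
#'
#' @param x A `grid_search` result.
#' @param ... Unused.
#' @return The full objective table, one row per grid point.
#' @export
tidy.grid_search <- function(x, ...) {
  tibble::as_tibble(x$table)
}

#' One-row summary of a grid search
#'
#' @param x A `grid_search` result.
#' @param ... Unused.
#' @return One-row tibble with the method, optimal parameters and attained
#'   objective.
#' @export
glance.grid_search <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(method = x$method),
    tibble::as_tibble(x$optimal),
    tibble::tibble(objective = x$objective, n_grid = nrow(x$table))
  )
}
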