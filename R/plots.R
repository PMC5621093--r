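# ggplot2 visualisations for pipeline results.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a fitted foot trajectory
#'
#' Two panels: clearance (vertical position) over stride time, and the
#' sagittal-plane path (forward displacement vs clearance).
#'
#' @param object A `foot_trajectory` from [run_pipeline()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.foot_trajectory <- function(object, ...) {
  traj <- tibble::as_tibble(object$trajectory)
  long <- dplyr::bind_rows(
    tibble::tibble(x = traj$time_s, y = traj$sy, panel = "clearance vs time [m]"),
    tibble::tibble(x = traj$sx, y = traj$sy, panel = "sagittal path [m]")
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_line(colour = "#2C6FB3") +
    ggplot2::facet_wrap(~panel, scales = "free_x") +
    ggplot2::labs(
      x = NULL, y = "clearance [m]",
      title = sprintf("Foot trajectory (%s + %s)",
                      object$methods$orientation, object$methods$integration)
    ) +
    ggplot2::theme_minimal()
}

#' Plot an orientation track as plane angles
#'
#' @param object An `orientation_track`.
#' @param ... Unused.
#' @return A ggplot object with one line per anatomical plane and rug marks
#'   where accelerometer updates were applied.
#' @export
autoplot.orientation_track <- function(object, ...) {
  d <- tidy.orientation_track(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_s, y = .data$angle_deg,
                                  colour = .data$plane)) +
    ggplot2::geom_line() +
    ggplot2::geom_rug(
      data = dplyr::filter(d, .data$accel_update & .data$plane == "sagittal"),
      sides = "b", colour = "grey40"
    ) +
    ggplot2::labs(x = "time [s]", y = "angle [deg]", colour = "plane") +
    ggplot2::theme_minimal()
}

#' Plot a grid-search objective surface
#'
#' For two-parameter grids a tile plot of the objective with the optimum
#' marked; for one parameter a line plot.
#'
#' @param object A `grid_search` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.grid_search <- function(object, ...) {
  tab <- tibble::as_tibble(object$table)
  pars <- setdiff(names(tab), "objective")
  if (length(pars) >= 2) {
    p <- ggplot2::ggplot(tab, ggplot2::aes(
      x = factor(signif(.data[[pars[1]]], 3)),
      y = factor(signif(.data[[pars[2]]], 3)),
      fill = .data$objective
    )) +
      ggplot2::geom_tile() +
      ggplot2::scale_fill_viridis_c() +
      ggplot2::labs(x = pars[1], y = pars[2],
                    title = sprintf("Grid search (%s)", object$method))
  } else {
    p <- ggplot2::ggplot(tab, ggplot2::aes(x = .data[[pars[1]]],
                                           y = .data$objective)) +
      ggplot2::geom_line() +
      ggplot2::geom_point() +
      ggplot2::labs(title = sprintf("Grid search (%s)", object$method))
  }
  p + ggplot2::theme_minimal()
}
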