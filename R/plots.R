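#' Plot a free-energy profile
#'
#' Draws the Jarzynski PMF against the steering coordinate (lambda runs
#' from the bound state at 1 to dissociation at 0, so the x axis is
#' reversed), with the plain work SD as a shaded band above the profile.
#'
#' @param object A `pmf_profile` from [jarzynski_pmf()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.pmf_profile <- function(object, ...) {
  unit <- attr(object, "unit")
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$lambda, y = .data$phi)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$phi,
                                      ymax = .data$phi + .data$sd_kcal),
                         alpha = 0.25) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = expression(lambda),
                  y = sprintf("Φ (%s)", unit)) +
    ggplot2::theme_minimal()
}

#' Plot a 2D Boltzmann-weighted work surface
#'
#' @param object A `surface2d` from [boltzmann_surface_2d()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.surface2d <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$x_mid, y = .data$y_mid,
                               fill = .data$z)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = sprintf("work (%s)", attr(object, "unit")),
                                  direction = -1) +
    ggplot2::labs(x = attr(object, "x_group"), y = attr(object, "y_group")) +
    ggplot2::theme_minimal()
}

#' Plot an ensemble of work-lambda curves
#'
#' One line per steered run, optionally colored by pathway class.
#'
#' @param curves Long work-curve tibble (`run`, `lambda`, `work`).
#' @param classes Optional result of [classify_pathway()]; colors runs by
#'   label.
#' @return A ggplot object.
#' @export
plot_work_curves <- function(curves, classes = NULL) {
  curves <- tibble::as_tibble(curves)
  if (!is.null(classes)) {
    curves <- dplyr::left_join(curves, classes[c("run", "label")], by = "run")
    p <- ggplot2::ggplot(curves,
                         ggplot2::aes(x = .data$lambda, y = .data$work,
                                      group = .data$run,
                                      color = .data$label))
  } else {
    p <- ggplot2::ggplot(curves,
                         ggplot2::aes(x = .data$lambda, y = .data$work,
                                      group = .data$run))
  }
  p + ggplot2::geom_line(alpha = 0.6) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = expression(lambda), y = "work") +
    ggplot2::theme_minimal()
}

#' Plot a groove-width profile
#'
#' @param profile Output of [minor_groove_width()] (per frame) or
#'   [groove_profile_mean()].
#' @return A ggplot object.
#' @export
plot_groove_profile <- function(profile) {
  if ("frame" %in% names(profile) && dplyr::n_distinct(profile$frame) > 1) {
    profile <- groove_profile_mean(profile)
  }
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$step, y = .data$width_nm)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "base-pair step", y = "minor groove width (nm)") +
    ggplot2::theme_minimal()
}
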