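#' Plot the observable traces of a run
#'
#' Facetted time series of per-bead energies and kinetic temperature.
#'
#' @param object A `dpd_trajectory`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot dpd_trajectory
#' @export
autoplot.dpd_trajectory <- function(object, ...) {
  obs <- tidyr::pivot_longer(
    object$observables,
    c("e_total", "e_kinetic", "e_pair", "e_bond", "e_angle", "temperature"),
    names_to = "quantity", values_to = "value")
  ggplot2::ggplot(obs, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "time (tau)", y = "per-bead value (kBT units)")
}

#' Plot a slab velocity profile
#'
#' The steady-state sawtooth of mean x-velocity against slab height z.
#'
#' @param object A `dpd_profile` from [velocity_profile()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot dpd_profile
#' @export
autoplot.dpd_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$z, y = .data$vx)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::labs(x = "z (r_c)", y = "<v_x> (r_c/tau)")
}

#' @rdname autoplot.dpd_trajectory
#' @param trajectory A `dpd_trajectory`.
#' @export
plot_energy <- function(trajectory) autoplot.dpd_trajectory(trajectory)

#' @rdname autoplot.dpd_profile
#' @param trajectory A `dpd_trajectory`.
#' @param window Trailing fraction averaged (see [velocity_profile()]).
#' @export
plot_velocity_profile <- function(trajectory, window = 0.5) {
  autoplot.dpd_profile(velocity_profile(trajectory, window))
}

#' Plot gyration series
#'
#' Time series of the chain-averaged radius of gyration and its diagonal
#' components from [mean_radius_of_gyration()].
#'
#' @param series Output of [mean_radius_of_gyration()].
#' @return A ggplot.
#' @export
plot_gyration <- function(series) {
  long <- tidyr::pivot_longer(series, c("rg", "rgxx", "rgyy", "rgzz"),
                              names_to = "component", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value,
                                     colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (tau)", y = "radius of gyration (r_c)")
}
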