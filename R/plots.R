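#' Serial-position curves across maintenance durations
#'
#' Normalized target probability of each item against `T_maintain` (log
#' scale), with the significance category of the adjacent-item contrast
#' annotated above each duration.
#'
#' @param experiment a `swm_experiment`.
#' @return a ggplot object.
#' @export
plot_serial_position <- function(experiment) {
  st <- experiment$stats
  sig <- experiment$contrasts |>
    dplyr::group_by(.data$t_maintain) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
  ggplot2::ggplot(st, ggplot2::aes(.data$t_maintain, .data$p,
                                   colour = factor(.data$item))) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$p - .data$p_sd,
                                          ymax = .data$p + .data$p_sd)) +
    ggplot2::geom_text(data = sig,
                       ggplot2::aes(.data$t_maintain,
                                    max(st$p + st$p_sd) + 0.02,
                                    label = .data$significance),
                       inherit.aes = FALSE, size = 3) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "T_maintain (s)", y = "normalized target probability",
                  colour = "item") +
    ggplot2::theme_minimal()
}

#' Relative synaptic efficacy during maintenance
#'
#' Trial-averaged `dJux(t)` (later minus earlier item) with its standard
#' error band; the zero crossing is the simulated critical moment
#' `T_c'(SIM)`.
#'
#' @param condition a `swm_condition` (typically the longest-maintenance
#'   one).
#' @return a ggplot object.
#' @export
plot_delta_jux <- function(condition) {
  d <- condition$delta_jux
  ggplot2::ggplot(d, ggplot2::aes(.data$t, .data$delta_jux)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$delta_jux - .data$sem,
                                      ymax = .data$delta_jux + .data$sem),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$pair)) +
    ggplot2::labs(x = "time from last-item offset (s)",
                  y = expression(Delta * "Jux(t)")) +
    ggplot2::theme_minimal()
}

#' Activity and efficacy time course of one trial
#'
#' Heatmap of the excitatory rates over the ring (requires the trial to be
#' run with `record = TRUE`) and the group efficacy traces.
#'
#' @param trial a `swm_trial` from [run_trial()].
#' @return a ggplot object.
#' @export
plot_trial <- function(trial) {
  if (!is.null(trial$trace)) {
    ggplot2::ggplot(trial$trace,
                    ggplot2::aes(.data$t, .data$theta * 180 / pi,
                                 fill = .data$r_e)) +
      ggplot2::geom_raster() +
      ggplot2::scale_fill_viridis_c(name = "rate") +
      ggplot2::labs(x = "time (s)", y = "preferred orientation (deg)") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(trial$group_trace,
                    ggplot2::aes(.data$t, .data$jux,
                                 colour = factor(.data$group))) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "time (s)", y = "Jux(t)", colour = "item group") +
      ggplot2::theme_minimal()
  }
}

#' Sweep heatmap of the transition moment
#'
#' @param sweep a `swm_sweep` tibble from [run_sweep()].
#' @param value which column to plot.
#' @return a ggplot object.
#' @export
plot_sweep <- function(sweep, value = "tc_exact") {
  axes <- setdiff(names(sweep),
                  c("tc_p", "tc_cv", "tc_ck", "tc_prime_sim", "tc_exact",
                    "tc_simplified"))
  stopifnot(length(axes) == 2)
  ggplot2::ggplot(sweep, ggplot2::aes(.data[[axes[1]]], .data[[axes[2]]],
                                      fill = .data[[value]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = value) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.swm_experiment <- function(object, ...) {
  plot_serial_position(object)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
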