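# Reduced model of the maintenance period: each item's neuronal group is an
# independent STP unit whose facilitation u decays to 0 with tau_f and whose
# resources x recover to 1 with tau_d once the network is silent.  The
# activity-silent memory trace is Jux(t) = J u(t) x(t); comparing the traces
# of successively encoded items gives the primacy-to-recency transition in
# closed form.

#' Theory parameters for the reduced model
#'
#' @param u0 release probability at stimulus offset, in (0, 1].
#' @param x0 available transmitter fraction at stimulus offset, in \[0, 1\].
#' @param tau_f,tau_d facilitation and depression time constants (s),
#'   `tau_f > tau_d > 0`.
#' @param t_star inter-item stride `t* = T_encode + T_gap` (s, > 0).
#' @param t_b cue-response bias (s): the time the recall cue needs to
#'   reactivate a group, on the order of the membrane time constant.
#' @param j_peak peak connection strength `J`.
#' @return object of class `theory_params`.
#' @export
theory_params <- function(u0 = 0.8, x0 = 0.2, tau_f = 4, tau_d = 0.3,
                          t_star = 1.25, t_b = 0.01, j_peak = 1.6) {
  stopifnot(
    u0 > 0, u0 <= 1, x0 >= 0, x0 <= 1,
    tau_f > tau_d, tau_d > 0, t_star > 0, t_b >= 0
  )
  structure(
    list(u0 = u0, x0 = x0, tau_f = tau_f, tau_d = tau_d,
         t_star = t_star, t_b = t_b, j_peak = j_peak),
    class = "theory_params"
  )
}

#' Silent-network STP relaxation
#'
#' With firing rates at zero, facilitation decays exponentially to 0 and
#' resources recover exponentially to 1:
#' `u(t) = u0 exp(-t/tau_f)`, `x(t) = 1 - (1 - x0) exp(-t/tau_d)`.
#'
#' @param u0,x0 state at stimulus offset.
#' @param t elapsed time since offset (s, >= 0); vectorized.
#' @param tau_f,tau_d time constants (s).
#' @return list with vectors `u` and `x`.
#' @export
#' @examples
#' stp_relax(0.8, 0.2, t = 4, tau_f = 4, tau_d = 0.3)$u  # 0.8/e
stp_relax <- function(u0, x0, t, tau_f, tau_d) {
  if (any(t < 0)) stop("t must be nonnegative", call. = FALSE)
  list(u = u0 * exp(-t / tau_f), x = 1 - (1 - x0) * exp(-t / tau_d))
}

#' Synaptic efficacy of one neuronal group during maintenance
#'
#' `Jux(t) = J u0 exp(-t/tau_f) * [1 - (1 - x0) exp(-t/tau_d)]`, with the
#' clock `t` running from that group's own stimulus offset.
#'
#' @param t time since the group's stimulus offset (s); vectorized.
#' @param params a [theory_params()].
#' @return efficacy values.
#' @export
jux_group <- function(t, params) {
  s <- stp_relax(params$u0, params$x0, t, params$tau_f, params$tau_d)
  params$j_peak * s$u * s$x
}

#' Relative efficacy of two sequentially encoded items
#'
#' `dJux(t) = Jux_2(t) - Jux_1(t)` with both clocks sharing the second
#' item's offset as origin, so group 1 is evaluated at `t + t*`.  Negative
#' values mean the first item's trace is stronger (primacy regime), positive
#' the second's (recency regime).
#'
#' @param t time since second-item offset (s); vectorized.
#' @param params a [theory_params()].
#' @return relative efficacy values.
#' @export
delta_jux_two <- function(t, params) {
  jux_group(t, params) - jux_group(t + params$t_star, params)
}

#' Closed-form critical moment of the efficacy crossover (two items)
#'
#' The root of `delta_jux_two`:
#' `T = tau_d * log( (1-x0) * (1 - exp(-t*/tau_d - t*/tau_f)) /
#' (1 - exp(-t*/tau_f)) )`.  When the trace difference is positive from the
#' start (e.g. `x0 = 1`, no depression) there is no crossing and `NA` is
#' returned.
#'
#' @param params a [theory_params()]; `tau_f`, `tau_d`, `t_star`, `x0` may
#'   also be vectors of equal length for grid evaluation.
#' @return crossing time (s), or `NA_real_` when no crossing exists.
#' @export
tc_exact <- function(params) {
  with(params, {
    arg <- (1 - x0) * (1 - exp(-t_star / tau_d - t_star / tau_f)) /
      (1 - exp(-t_star / tau_f))
    tc <- ifelse(arg > 0, tau_d * log(arg), -Inf)
    ifelse(is.finite(tc) & tc > 0, tc, NA_real_)
  })
}

#' Simplified critical moment with cue-response bias
#'
#' In the facilitation-dominant regime (`tau_f >> tau_d`) the crossover
#' simplifies to `T = tau_d * log((1-x0)/(1 - exp(-t*/tau_f))) + t_b`,
#' where `t_b` is the constant bias accounting for the time the recall cue
#' needs to drive a group's response.
#'
#' @inheritParams tc_exact
#' @return crossing time (s), or `NA_real_` when no crossing exists.
#' @export
tc_simplified <- function(params) {
  with(params, {
    arg <- (1 - x0) / (1 - exp(-t_star / tau_f))
    tc <- ifelse(arg > 0, tau_d * log(arg) + t_b, -Inf)
    ifelse(is.finite(tc) & tc > 0, tc, NA_real_)
  })
}

#' Critical moments for the three-item task
#'
#' By the shift relation `Jux_i(t) = Jux_j(t + (j - i) t*)`, the pairwise
#' crossovers are
#' `Tc12' = tau_d log((1-x0)/(1-exp(-t*/tau_f))) - t* + t_b12` and
#' `Tc23' = tau_d log((1-x0)/(1-exp(-t*/tau_f))) + t_b23`; with equal biases
#' `Tc12' = Tc23' - t*`.
#'
#' @param params a [theory_params()].
#' @param t_b12,t_b23 cue-response biases for the two contrasts (s);
#'   default to `params$t_b`.
#' @return tibble with columns `pair`, `tc` (NA when the crossing falls at
#'   or before maintenance onset).
#' @export
tc_three_items <- function(params, t_b12 = params$t_b, t_b23 = params$t_b) {
  base <- with(params,
               tau_d * log((1 - x0) / (1 - exp(-t_star / tau_f))))
  tc12 <- base - params$t_star + t_b12
  tc23 <- base + t_b23
  tibble::tibble(
    pair = c("12", "23"),
    tc = ifelse(is.finite(c(tc12, tc23)) & c(tc12, tc23) > 0,
                c(tc12, tc23), NA_real_)
  )
}

#' Relative efficacies for the three-item task
#'
#' `dJux_12(t) = Jux_2(t) - Jux_1(t)` and `dJux_23(t) = Jux_3(t) - Jux_2(t)`
#' with the clock `t` running from the last (third) item's offset, built
#' constructively from [jux_group()] via the shift relation.
#'
#' @param t time since third-item offset (s); vectorized.
#' @param params a [theory_params()].
#' @return tibble with columns `t`, `pair`, `delta_jux`.
#' @export
delta_jux_three <- function(t, params) {
  n <- length(t)
  j3 <- jux_group(t, params)
  j2 <- jux_group(t + params$t_star, params)
  j1 <- jux_group(t + 2 * params$t_star, params)
  tibble::tibble(
    t = c(t, t),
    pair = rep(c("12", "23"), each = n),
    delta_jux = c(j2 - j1, j3 - j2)
  )
}

#' Theory grid over STP and task parameters
#'
#' Vectorized evaluation of [tc_exact()] and [tc_simplified()] over a
#' parameter grid.
#'
#' @param tau_f,tau_d,t_gap vectors of values (s); crossed into a grid.
#' @param t_encode stimulus duration (s), added to `t_gap` to give `t*`.
#' @param x0,u0 offset state (scalars).
#' @param t_b cue-response bias (s).
#' @return tibble with one row per grid point: `tau_f`, `tau_d`, `t_gap`,
#'   `t_star`, `u0`, `x0`, `tc_exact`, `tc_simplified`.
#' @export
theory_grid <- function(tau_f, tau_d, t_gap, t_encode = 0.25,
                        x0 = 0.2, u0 = 0.8, t_b = 0.01) {
  g <- tidyr::expand_grid(tau_f = tau_f, tau_d = tau_d, t_gap = t_gap)
  g$t_star <- g$t_gap + t_encode
  g$u0 <- u0
  g$x0 <- x0
  pl <- list(u0 = u0, x0 = x0, tau_f = g$tau_f, tau_d = g$tau_d,
             t_star = g$t_star, t_b = t_b)
  g$tc_exact <- tc_exact(pl)
  g$tc_simplified <- tc_simplified(pl)
  g
}

#' Estimate offset STP state from simulated traces
#'
#' Bridges the full network to the reduced theory: samples the
#' group-averaged `u` and `x` of each item's neuronal group at that item's
#' stimulus offset, so theory/simulation comparisons use matched constants.
#'
#' @param snapshots snapshot list from [run_dynamics()] (fields `t`, `u`,
#'   `x`, one row per snapshot time = one per item offset).
#' @param groups a [group_config()] with one centre per item.
#' @param grid a [ring_grid()].
#' @return tibble with `item`, `u0`, `x0`.
#' @export
estimate_u0_x0 <- function(snapshots, groups, grid) {
  m <- length(groups$centers)
  stopifnot(nrow(snapshots$u) == m)
  mask <- group_mask(groups, grid)
  sizes <- rowSums(mask)
  tibble::tibble(
    item = seq_len(m),
    u0 = as.vector((snapshots$u * mask) %*% rep(1, ncol(mask))) / sizes,
    x0 = as.vector((snapshots$x * mask) %*% rep(1, ncol(mask))) / sizes
  )
}
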