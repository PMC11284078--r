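#' Translation-invariant ring connectivity
#'
#' Builds the excitatory-to-excitatory connection matrix
#' `J(theta, theta') = J * cos(B * d)` for `B*d` within
#' `[-arccos(-J0/J), arccos(-J0/J)]` and `J0` outside, where `d` is the
#' wrapped orientation difference.  The matrix is symmetric and circulant:
#' connectivity depends only on the difference in preferred orientations.
#'
#' @param params a [cann_params()] object.
#' @param grid a [ring_grid()]; defaults to the grid implied by `params`.
#' @return an `n x n` numeric matrix.
#' @export
#' @examples
#' W <- make_connectivity(cann_params(n_neurons = 16))
#' all.equal(W, t(W))
make_connectivity <- function(params, grid = ring_grid(params$n_neurons)) {
  validate_cann_params(params)
  th <- grid$thetas
  d <- wrap_orientation(outer(th, th, "-"))
  cutoff <- acos(-params$j_floor / params$j_peak)
  arg <- params$b_width * d
  w <- matrix(params$j_floor, length(th), length(th))
  inside <- abs(arg) <= cutoff
  w[inside] <- params$j_peak * cos(arg[inside])
  w
}

#' Smoothed threshold-linear firing-rate function
#'
#' `r = alpha * log(1 + exp(h / alpha))`: softplus with gain `alpha`,
#' computed overflow-safely.  Strictly increasing, nonnegative, and linear
#' for `h >> alpha`.
#'
#' @param h synaptic input (scalar or vector).
#' @param alpha gain (> 0).
#' @return firing rate(s), same shape as `h`.
#' @export
#' @examples
#' firing_rate(0, alpha = 1.5)  # 1.5 * log(2)
firing_rate <- function(h, alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0) {
    stop("alpha must be a single positive number", call. = FALSE)
  }
  z <- h / alpha
  r <- numeric(length(z))
  hi <- z > 30
  lo <- z < -30
  mid <- !hi & !lo
  r[hi] <- alpha * z[hi]
  r[lo] <- alpha * exp(z[lo])
  r[mid] <- alpha * log1p(exp(z[mid]))
  dim(r) <- dim(h)
  r
}

#' Initial network state
#'
#' The resting state of the network: inputs at zero, release probability at
#' its baseline 0 and transmitter resources full (`x = 1`).
#'
#' @param params a [cann_params()] object.
#' @param t starting simulation clock (s).
#' @return object of class `cann_state`: list with `h_e`, `h_i`, `u`, `x`, `t`.
#' @export
initial_state <- function(params, t = 0) {
  n <- params$n_neurons
  structure(
    list(h_e = numeric(n), h_i = 0, u = numeric(n), x = rep(1, n), t = t),
    class = "cann_state"
  )
}

validate_cann_state <- function(state, n) {
  stopifnot(
    length(state$h_e) == n, length(state$u) == n, length(state$x) == n,
    all(is.finite(state$h_e)), is.finite(state$h_i),
    all(state$u >= 0 & state$u <= 1), all(state$x >= 0 & state$x <= 1)
  )
  invisible(state)
}

#' One Euler-Maruyama step of the network dynamics (reference implementation)
#'
#' Pure-R single step used as the readable reference for the compiled
#' integrator: synaptic inputs relax with time constant `tau` under the
#' recurrent current (connectivity weighted by the instantaneous synaptic
#' efficacy `u*x`), global inhibition, external input and background drive;
#' facilitation `u` and depression `x` follow the Tsodyks-Markram dynamics;
#' `u`, `x` are clipped to `[0, 1]` after the step.
#'
#' @param state a `cann_state`.
#' @param ext_input external input vector over the ring.
#' @param params a [cann_params()] object.
#' @param connectivity matrix from [make_connectivity()].
#' @param noise vector of i.i.d. standard normal draws (one per neuron), or
#'   `NULL` for a noise-free step.
#' @return the updated `cann_state`.
#' @export
network_step <- function(state, ext_input, params, connectivity,
                         noise = NULL) {
  p <- params
  n <- p$n_neurons
  stopifnot(length(ext_input) == n)
  validate_cann_state(state, n)
  w <- pi / n
  r_e <- firing_rate(state$h_e, p$alpha)
  r_i <- firing_rate(state$h_i, p$alpha)
  recurrent <- p$rho * w * drop(connectivity %*% (state$u * state$x * r_e))

  dh <- (p$dt / p$tau) *
    (-state$h_e + recurrent - p$j_ei * r_i + ext_input + p$i0)
  if (!is.null(noise)) {
    dh <- dh + p$sigma0 * sqrt(p$dt) / p$tau * noise
  }
  h_e <- state$h_e + dh
  h_i <- state$h_i + (p$dt / p$tau) * (-state$h_i + p$j_ie * w * sum(r_e))
  u <- state$u + p$dt * (-state$u / p$tau_f +
                           p$u_increment * (1 - state$u) * r_e)
  x <- state$x + p$dt * ((1 - state$x) / p$tau_d - state$u * state$x * r_e)

  if (!all(is.finite(h_e)) || !is.finite(h_i)) {
    stop("network integration blew up at t = ", state$t + p$dt,
         " (max |h_E| = ", max(abs(h_e[is.finite(h_e)]), 0), ")",
         call. = FALSE)
  }
  structure(
    list(h_e = h_e, h_i = h_i, u = pmin(pmax(u, 0), 1),
         x = pmin(pmax(x, 0), 1), t = state$t + p$dt),
    class = "cann_state"
  )
}

#' Integrate the network over a stimulus schedule
#'
#' Runs the compiled Euler-Maruyama loop for `duration` seconds under a
#' piecewise-constant stimulus schedule, optionally recording field traces,
#' group-aggregated traces, state snapshots and a time-averaged rate profile.
#' Bit-reproducible given (seed, params, schedule, dt).
#'
#' @param state a `cann_state` to start from (see [initial_state()]).
#' @param params a [cann_params()] object.
#' @param duration simulated time (s), `>= 0`.
#' @param schedule tibble of stimulus intervals as built by
#'   [build_schedule()], or `NULL` for no external input.
#' @param connectivity connection matrix; rebuilt from `params` if `NULL`.
#' @param seed integer seed for the integrator's own RNG stream.
#' @param record_stride record full field traces every this many steps
#'   (0 = off).
#' @param group_stride record group-averaged rate and efficacy traces every
#'   this many steps (0 = off); requires `groups`.
#' @param groups a [group_config()] object (for group traces).
#' @param snapshot_times times at which to store the full `u`, `x` vectors.
#' @param decode_window length-2 numeric: average the rate profile over this
#'   time window (for population-vector decoding), or `NULL`.
#' @return list with the final `state` and, as requested, `trace` (tibble:
#'   t, neuron, theta, h_e, r_e, u, x), `h_i_trace`, `group_trace` (tibble:
#'   t, group, rate, jux), `snapshots`, and `decode_profile`.
#' @export
run_dynamics <- function(state, params, duration, schedule = NULL,
                         connectivity = NULL, seed = 1,
                         record_stride = 0L, group_stride = 0L,
                         groups = NULL, snapshot_times = numeric(0),
                         decode_window = NULL) {
  validate_cann_params(params)
  n <- params$n_neurons
  validate_cann_state(state, n)
  stopifnot(duration >= 0)
  grid <- ring_grid(n)
  if (is.null(connectivity)) connectivity <- make_connectivity(params, grid)

  sched_mat <- schedule_matrix(schedule)
  gmask <- if (is.null(groups)) {
    matrix(0, 0, n)
  } else {
    group_mask(groups, grid)
  }
  dw <- if (is.null(decode_window)) c(0, -1) else as.numeric(decode_window)
  if (!is.null(decode_window)) {
    stopifnot(length(dw) == 2L, dw[2] > dw[1])
  }

  if (duration == 0) {
    out <- list(state = state)
    if (record_stride > 0) out$trace <- empty_trace()
    return(out)
  }

  raw <- cpp_run_network(
    state$h_e, state$h_i, state$u, state$x, state$t,
    connectivity, grid$thetas, unclass(params), sched_mat, duration,
    as.integer(record_stride), as.integer(group_stride), gmask,
    as.numeric(snapshot_times), dw[1], dw[2], as.numeric(seed)
  )

  out <- list(state = structure(
    list(h_e = drop(raw$h_e), h_i = raw$h_i, u = drop(raw$u),
         x = drop(raw$x), t = raw$t),
    class = "cann_state"
  ))
  if (!is.null(raw$trace)) {
    tr <- raw$trace
    nt <- length(tr$t)
    out$trace <- tibble::tibble(
      t = rep(drop(tr$t), each = n),
      neuron = rep(seq_len(n), times = nt),
      theta = rep(grid$thetas, times = nt),
      h_e = as.vector(t(tr$h_e)),
      r_e = as.vector(t(tr$r_e)),
      u = as.vector(t(tr$u)),
      x = as.vector(t(tr$x))
    )
    out$h_i_trace <- tibble::tibble(t = drop(tr$t), h_i = drop(tr$h_i))
  }
  if (!is.null(raw$group_trace)) {
    gt <- raw$group_trace
    ng <- ncol(gt$r)
    out$group_trace <- tibble::tibble(
      t = rep(drop(gt$t), times = ng),
      group = rep(seq_len(ng), each = length(gt$t)),
      rate = as.vector(gt$r),
      jux = params$j_peak * as.vector(gt$ux)
    )
  }
  if (!is.null(raw$snapshots)) {
    out$snapshots <- list(
      t = drop(raw$snapshots$t),
      u = raw$snapshots$u, x = raw$snapshots$x
    )
  }
  if (!is.null(raw$decode_profile)) {
    out$decode_profile <- drop(raw$decode_profile)
  }
  out
}

empty_trace <- function() {
  tibble::tibble(t = numeric(0), neuron = integer(0), theta = numeric(0),
                 h_e = numeric(0), r_e = numeric(0), u = numeric(0),
                 x = numeric(0))
}

# schedule tibble -> matrix (t_start, t_end, amplitude, sharpness, center,
# noise_sigma) for the compiled loop
schedule_matrix <- function(schedule) {
  if (is.null(schedule) || nrow(schedule) == 0) {
    return(matrix(0, 0, 6))
  }
  active <- schedule[!is.na(schedule$amplitude) & schedule$amplitude > 0, ]
  as.matrix(active[, c("t_start", "t_end", "amplitude", "sharpness",
                       "center", "noise_sigma")])
}
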