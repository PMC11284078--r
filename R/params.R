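#' Network and plasticity parameters
#'
#' Bundles every static constant of the ring attractor: the membrane/synaptic
#' time constant, connectivity shape, inhibitory-pool couplings, the smoothed
#' threshold-linear gain, background drive and noise, and the short-term
#' plasticity constants.  Defaults are the package's calibrated operating
#' point: an encoding stimulus evokes a transient bump, activity returns to
#' silence after stimulus offset (no persistent firing), and a weak recall cue
#' reactivates a bump centred on the most facilitated neuronal group.
#'
#' @param n_neurons number of excitatory neurons on the orientation ring.
#' @param tau membrane/synaptic time constant (s).
#' @param rho neuronal density (neurons per radian); defaults to `n_neurons/pi`.
#' @param j_peak peak recurrent connection strength `J`.
#' @param j_floor connection floor `J0` outside the cosine interaction range
#'   (negative: surround suppression).
#' @param b_width interaction-range control `B` of the cosine kernel.
#' @param j_ei inhibitory-to-excitatory coupling.
#' @param j_ie excitatory-to-inhibitory coupling.
#' @param alpha gain of the smoothed threshold-linear rate function
#'   `r = alpha * log(1 + exp(h/alpha))`.
#' @param i0 constant background drive (subthreshold; negative keeps the
#'   resting state nearly silent).
#' @param sigma0 background noise strength.
#' @param tau_f facilitation time constant (s); must exceed `tau_d`
#'   (facilitation-dominant regime).
#' @param tau_d depression recovery time constant (s).
#' @param u_increment facilitation increment `U0` per unit rate, in (0, 1].
#' @param dt integration step (s); must satisfy `dt <= tau/10`.
#'
#' @return An object of class `cann_params` (named list).
#' @export
#' @examples
#' p <- cann_params()
#' p$tau_f
cann_params <- function(n_neurons = 128L,
                        tau = 0.01,
                        rho = n_neurons / pi,
                        j_peak = 1.6,
                        j_floor = -0.16,
                        b_width = 12,
                        j_ei = 1.2,
                        j_ie = 0.5,
                        alpha = 1.5,
                        i0 = -6,
                        sigma0 = 0.1,
                        tau_f = 4,
                        tau_d = 0.3,
                        u_increment = 0.3,
                        dt = 5e-4) {
  p <- list(
    n_neurons = as.integer(n_neurons), tau = tau, rho = rho,
    j_peak = j_peak, j_floor = j_floor, b_width = b_width,
    j_ei = j_ei, j_ie = j_ie, alpha = alpha, i0 = i0, sigma0 = sigma0,
    tau_f = tau_f, tau_d = tau_d, u_increment = u_increment, dt = dt
  )
  class(p) <- "cann_params"
  validate_cann_params(p)
  p
}

validate_cann_params <- function(p) {
  stopifnot(
    p$n_neurons >= 8L,
    p$dt > 0, p$tau > 0,
    p$tau_f > p$tau_d, p$tau_d > 0,
    p$u_increment > 0, p$u_increment <= 1,
    p$alpha > 0, p$rho > 0, p$b_width > 0,
    p$sigma0 >= 0
  )
  if (abs(p$j_floor / p$j_peak) > 1) {
    stop("invalid J0/J ratio: |j_floor/j_peak| must be <= 1 so that ",
         "arccos(-J0/J) is defined", call. = FALSE)
  }
  if (p$dt > p$tau / 10) {
    stop("integration step dt must be <= tau/10 for stability", call. = FALSE)
  }
  invisible(p)
}

#' @export
print.cann_params <- function(x, ...) {
  cat("<cann_params>", x$n_neurons, "neurons, tau =", x$tau, "s, dt =",
      x$dt, "s\n")
  cat("  connectivity: J =", x$j_peak, " J0 =", x$j_floor, " B =", x$b_width,
      " J_EI =", x$j_ei, " J_IE =", x$j_ie, "\n")
  cat("  STP: tau_f =", x$tau_f, "s, tau_d =", x$tau_d, "s, U0 =",
      x$u_increment, "\n")
  invisible(x)
}

#' Uniform grid of preferred orientations on the half-circle
#'
#' Orientation is pi-periodic, so the feature space is `[-pi/2, pi/2)` with
#' periodic boundary conditions.
#'
#' @param n_neurons number of grid points.
#' @return An object of class `ring_grid`: list with `thetas` (strictly
#'   increasing angles) and `spacing` (`pi/n`).
#' @export
ring_grid <- function(n_neurons) {
  n <- as.integer(n_neurons)
  stopifnot(n >= 8L)
  structure(
    list(thetas = -pi / 2 + (seq_len(n) - 1L) * pi / n, spacing = pi / n),
    class = "ring_grid"
  )
}

#' Wrap orientation differences into [-pi/2, pi/2)
#'
#' Orientations live on a ring of period pi; every difference between angles
#' is reduced modulo pi to the symmetric interval.
#'
#' @param x angles or angle differences (radians).
#' @return wrapped values in `[-pi/2, pi/2)`.
#' @export
#' @examples
#' wrap_orientation(pi / 2 + 0.1)  # -pi/2 + 0.1
wrap_orientation <- function(x) {
  w <- x - pi * floor(x / pi + 0.5)
  w[w >= pi / 2] <- w[w >= pi / 2] - pi
  w
}

#' Read / write parameter configuration files
#'
#' Parameters are stored in a flat key-value YAML file with namespaced keys
#' (`network.*`, `stp.*`, `integration.*`); units are seconds and radians.
#'
#' @param params a [cann_params()] object.
#' @param path file path.
#' @return `write_params_config` returns `path` invisibly;
#'   `read_params_config` returns a [cann_params()] object.
#' @export
write_params_config <- function(params, path) {
  validate_cann_params(params)
  cfg <- list(
    network = params[c("n_neurons", "tau", "rho", "j_peak", "j_floor",
                       "b_width", "j_ei", "j_ie", "alpha", "i0", "sigma0")],
    stp = params[c("tau_f", "tau_d", "u_increment")],
    integration = params["dt"]
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_params_config
#' @export
read_params_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(cann_params, c(cfg$network, cfg$stp, cfg$integration))
}
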