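# Small parameter sets for structural tests (dynamical behaviour that
# depends on the calibrated operating point uses cann_params() defaults).

tiny_params <- function(n = 32L, sigma0 = 0, ...) {
  cann_params(n_neurons = n, sigma0 = sigma0, ...)
}

# two-item protocol with fixed angles and no input noise
quiet_protocol <- function(t_maintain = 0.5, cued_item = 1L, sep_deg = 40,
                           ...) {
  pr <- task_protocol(
    c(-0.2, wrap_orientation(-0.2 + sep_deg * pi / 180)),
    t_maintain = t_maintain, cued_item = cued_item, ...
  )
  pr$encode_spec$noise_sigma <- 0
  pr$recall_spec$noise_sigma <- 0
  pr
}

# independent trigonometric-moment oracle for circular statistics
# (explicit sums, no complex arithmetic)
oracle_circ <- function(errors) {
  phi <- 2 * errors
  c1 <- sum(cos(phi)) / length(phi)
  s1 <- sum(sin(phi)) / length(phi)
  c2 <- sum(cos(2 * phi)) / length(phi)
  s2 <- sum(sin(2 * phi)) / length(phi)
  rbar <- sqrt(c1^2 + s1^2)
  mu1 <- atan2(s1, c1)
  rho2 <- sqrt(c2^2 + s2^2)
  mu2 <- atan2(s2, c2)
  list(
    cv = 1 - rbar,
    ck = (rho2 * cos(mu2 - 2 * mu1) - rbar^4) / (1 - rbar)^2
  )
}
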