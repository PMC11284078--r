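# Circular statistics on recall errors.  Orientation errors live on a ring
# of period pi, so all moments are computed on doubled angles (period 2pi);
# reported errors elsewhere stay un-doubled.

trig_moment <- function(phi, p = 1) {
  z <- mean(exp(1i * p * phi))
  list(rho = Mod(z), mu = Arg(z))
}

#' Circular variance of recall errors
#'
#' On doubled angles `phi = 2*error`: `CV = 1 - Rbar`, the complement of the
#' mean resultant length.  0 for identical errors, 1 for errors uniform on
#' the circle.
#'
#' @param errors recall errors (radians, orientation scale, period pi).
#' @return circular variance in `[0, 1]`.
#' @export
circular_variance <- function(errors) {
  errors <- errors[!is.na(errors)]
  if (length(errors) < 2) stop("need at least 2 errors", call. = FALSE)
  1 - trig_moment(2 * errors, 1)$rho
}

#' Circular kurtosis of recall errors
#'
#' On doubled angles, the CircStat definition
#' `k = (rho2 * cos(mu2 - 2*mu1) - Rbar^4) / (1 - Rbar)^2`, with `mu1`,
#' `mu2` the first/second trigonometric moment directions, `rho2` the
#' second-moment resultant length, and `Rbar` the first-moment resultant.
#' Near 1 for tightly concentrated samples, near 0 for uniform ones.
#'
#' @inheritParams circular_variance
#' @return circular kurtosis.
#' @export
circular_kurtosis <- function(errors) {
  errors <- errors[!is.na(errors)]
  if (length(errors) < 2) stop("need at least 2 errors", call. = FALSE)
  phi <- 2 * errors
  m1 <- trig_moment(phi, 1)
  m2 <- trig_moment(phi, 2)
  (m2$rho * cos(m2$mu - 2 * m1$mu) - m1$rho^4) / (1 - m1$rho)^2
}
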