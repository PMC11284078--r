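# Normalized target probability: recall responses are modelled as a mixture
# of a von Mises component at the target orientation, one at each non-target,
# and a uniform (guessing) component, all on doubled angles (orientation is
# pi-periodic) with a shared concentration kappa.  An item's normalized
# target probability P is the mean posterior probability of the target
# component across that item's trials.

# ratio of modified Bessel functions A(kappa) = I1/I0, overflow-safe
bessel_ratio <- function(kappa) {
  besselI(kappa, 1, expon.scaled = TRUE) /
    besselI(kappa, 0, expon.scaled = TRUE)
}

# inverse of bessel_ratio: Banerjee et al. start + Newton refinement;
# kappa is capped (samples more concentrated than that are numerically
# indistinguishable from a point mass)
KAPPA_MAX <- 5e3

a1inv <- function(r) {
  r <- min(max(r, 0), 1 - 1e-10)
  k <- if (r < 0.53) {
    2 * r + r^3 + 5 * r^5 / 6
  } else if (r < 0.85) {
    -0.4 + 1.39 * r + 0.43 / (1 - r)
  } else {
    1 / (r^3 - 4 * r^2 + 3 * r)
  }
  k <- min(k, KAPPA_MAX)
  for (i in 1:25) {
    a <- bessel_ratio(k)
    da <- 1 - a^2 - a / k
    if (!is.finite(a) || !is.finite(da) || da <= 0) break
    step <- (a - r) / da
    k <- min(max(k - step, 1e-8), KAPPA_MAX)
    if (abs(step) < 1e-10) break
  }
  k
}

# log von Mises density on the full circle
dvm_log <- function(phi, mu, kappa) {
  kappa * (cos(phi - mu) - 1) -
    log(2 * pi) - log(besselI(kappa, 0, expon.scaled = TRUE))
}

#' Fit the recall-response mixture for one item
#'
#' Maximum-likelihood fit (EM) of the response mixture for the trials on
#' which a given item was cued: a von Mises component centred on the target,
#' one on each non-target (shared concentration, equal split of the
#' non-target weight), and a uniform component.  Fitting is done on doubled
#' angles.  If EM fails to converge, falls back to the nearest-item
#' assignment proportion, flagged in the result.
#'
#' @param errors response errors relative to the target,
#'   `wrap_orientation(response - target)`, one per trial (radians).
#' @param nontarget_offsets matrix (`n_trials x (M-1)`) of wrapped non-target
#'   offsets `wrap_orientation(theta_nontarget - target)`; may have zero
#'   columns for a single-item task.
#' @param max_iter,tol EM iteration cap and log-likelihood tolerance.
#' @return object of class `vm_mixture`: weights (`w_target`,
#'   `w_nontarget`, `w_uniform`), shared `kappa`, `p_target` (mean posterior
#'   of the target component = the normalized target probability),
#'   per-trial posteriors, log-likelihood, convergence flag and method.
#' @export
fit_response_mixture <- function(errors, nontarget_offsets = NULL,
                                 max_iter = 500, tol = 1e-8) {
  keep <- !is.na(errors)
  errors <- errors[keep]
  n <- length(errors)
  if (n < 20) stop("need at least 20 trials per item", call. = FALSE)
  if (is.null(nontarget_offsets)) {
    nontarget_offsets <- matrix(numeric(0), n, 0)
  } else {
    nontarget_offsets <- as.matrix(nontarget_offsets)[keep, , drop = FALSE]
  }
  k_nt <- ncol(nontarget_offsets)
  phi <- 2 * errors                        # doubled angles, period 2*pi
  mu_nt <- 2 * nontarget_offsets
  n_comp <- 1L + k_nt + 1L                 # target, non-targets, uniform

  w <- c(0.6, rep(0.3 / max(k_nt, 1), k_nt), 0.1)
  w <- w / sum(w)
  kappa <- 5
  log_unif <- -log(2 * pi)
  ll_old <- -Inf
  converged <- FALSE

  for (it in seq_len(max_iter)) {
    logd <- matrix(log_unif, n, n_comp)
    logd[, 1] <- dvm_log(phi, 0, kappa)
    if (k_nt > 0) {
      for (j in seq_len(k_nt)) {
        logd[, 1 + j] <- dvm_log(phi, mu_nt[, j], kappa)
      }
    }
    logp <- sweep(logd, 2, log(pmax(w, 1e-300)), "+")
    mx <- apply(logp, 1, max)
    pr <- exp(logp - mx)
    row_tot <- rowSums(pr)
    gamma <- pr / row_tot
    ll <- sum(mx + log(row_tot))

    w <- colMeans(gamma)
    # shared kappa from the von Mises responsibilities
    g_vm <- gamma[, seq_len(1 + k_nt), drop = FALSE]
    cosdev <- cos(phi)                     # target centred at 0
    if (k_nt > 0) {
      cosdev <- cbind(cosdev, cos(phi - mu_nt))
    } else {
      cosdev <- matrix(cosdev, ncol = 1)
    }
    tot <- sum(g_vm)
    if (tot > 1e-12) {
      r_w <- sum(g_vm * cosdev) / tot
      kappa <- a1inv(r_w)
    }
    if (is.finite(ll) && abs(ll - ll_old) < tol * (1 + abs(ll))) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
  }

  if (!converged && !is.finite(ll_old)) {
    # nearest-item fallback
    if (k_nt > 0) {
      dists <- cbind(abs(errors), abs(wrap_orientation(
        matrix(errors, n, k_nt) - nontarget_offsets)))
      p_target <- mean(apply(dists, 1, which.min) == 1)
    } else {
      p_target <- 1
    }
    return(structure(
      list(weights = rep(NA_real_, n_comp), kappa = NA_real_,
           p_target = p_target, posterior = NULL, loglik = NA_real_,
           n = n, converged = FALSE, method = "nearest"),
      class = "vm_mixture"
    ))
  }

  colnames(gamma) <- c("target",
                       if (k_nt > 0) paste0("nontarget", seq_len(k_nt)),
                       "uniform")
  structure(
    list(
      weights = c(w_target = w[1],
                  w_nontarget = if (k_nt > 0) sum(w[2:(1 + k_nt)]) else 0,
                  w_uniform = w[n_comp]),
      kappa = kappa,
      p_target = mean(gamma[, 1]),
      posterior = tibble::as_tibble(as.data.frame(gamma)),
      loglik = ll_old, n = n, converged = converged, method = "mixture"
    ),
    class = "vm_mixture"
  )
}

#' Normalized target probability of an item
#'
#' Convenience wrapper around [fit_response_mixture()] returning only `P`,
#' the mean posterior probability that the item's responses were generated
#' by the target component.
#'
#' @inheritParams fit_response_mixture
#' @return `P` in `[0, 1]`.
#' @export
normalized_target_probability <- function(errors, nontarget_offsets = NULL) {
  fit_response_mixture(errors, nontarget_offsets)$p_target
}

#' @export
print.vm_mixture <- function(x, ...) {
  cat("<vm_mixture> n =", x$n, " method =", x$method, "\n")
  cat("  P(target) =", signif(x$p_target, 4),
      " kappa =", signif(x$kappa, 4), "\n")
  cat("  weights:", paste(names(x$weights),
                          signif(x$weights, 3), collapse = ", "), "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted response mixture
#'
#' @param x a `vm_mixture` object.
#' @param ... unused.
#' @return one row per mixture component with its fitted weight.
#' @export
tidy.vm_mixture <- function(x, ...) {
  tibble::tibble(
    component = names(x$weights),
    weight = unname(x$weights),
    kappa = c(x$kappa, x$kappa, NA_real_)
  )
}

#' @rdname tidy.vm_mixture
#' @return `glance`: one-row tibble with fit summary.
#' @export
glance.vm_mixture <- function(x, ...) {
  tibble::tibble(
    p_target = x$p_target, kappa = x$kappa, loglik = x$loglik,
    n = x$n, converged = x$converged, method = x$method
  )
}

# Best-Fisher von Mises sampler (full circle)
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-8) return(wrap_circle(stats::runif(n, -pi, pi) + mu))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 0
  while (i < n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      i <- i + 1
      out[i] <- mu + sign(u[3] - 0.5) * acos(f)
    }
  }
  wrap_circle(out)
}

wrap_circle <- function(x) {
  ((x + pi) %% (2 * pi)) - pi
}

#' Generate synthetic recall responses
#'
#' Samples response orientations from the same mixture family that
#' [fit_response_mixture()] fits: von Mises at the target, von Mises at each
#' non-target, uniform guesses.  Used to test the statistics layer without
#' the network simulator (parameter-recovery fixture).
#'
#' @param true_angles item orientations (radians); the first is the target.
#' @param kappa shared concentration (on doubled angles).
#' @param weights mixture weights `(target, each non-target ..., uniform)`;
#'   must sum to 1.
#' @param n_trials number of responses to draw.
#' @return tibble with `response` (radians) and `component` (which component
#'   generated it).
#' @export
generate_synthetic_responses <- function(true_angles, kappa, weights,
                                         n_trials) {
  m <- length(true_angles)
  stopifnot(length(weights) == m + 1L, all(weights >= 0))
  if (abs(sum(weights) - 1) > 1e-8) {
    stop("mixture weights must sum to 1", call. = FALSE)
  }
  comp <- sample.int(m + 1L, n_trials, replace = TRUE, prob = weights)
  response <- numeric(n_trials)
  for (j in seq_len(m)) {
    idx <- comp == j
    if (any(idx)) {
      phi <- rvonmises(sum(idx), 2 * true_angles[j], kappa)
      response[idx] <- wrap_orientation(phi / 2)
    }
  }
  idx <- comp == m + 1L
  if (any(idx)) response[idx] <- stats::runif(sum(idx), -pi / 2, pi / 2)
  tibble::tibble(
    response = response,
    component = c(paste0("item", seq_len(m)), "uniform")[comp]
  )
}
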