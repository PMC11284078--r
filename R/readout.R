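#' Neuronal group configuration
#'
#' Group `G_i` is the ensemble of neurons whose preferred orientation lies
#' within `half_width` of the i-th item's orientation (wrapped difference).
#' The default half-width of 10 degrees covers the stimulated core of an
#' encoded bump while staying below the smallest two-item orientation
#' difference (17 degrees), so groups for distinct items never fully
#' overlap and group averages are not diluted by unstimulated neurons.
#'
#' @param centers item orientations (radians).
#' @param half_width group half-width `Delta` (radians), in `(0, pi/4)`.
#' @return object of class `group_config`.
#' @export
group_config <- function(centers, half_width = 10 * pi / 180) {
  stopifnot(half_width > 0, half_width < pi / 4, length(centers) >= 1)
  structure(
    list(centers = wrap_orientation(centers), half_width = half_width),
    class = "group_config"
  )
}

# membership matrix (n_groups x n), rows are 0/1 masks
group_mask <- function(groups, grid) {
  m <- t(vapply(
    groups$centers,
    function(c0) {
      as.numeric(abs(wrap_orientation(grid$thetas - c0)) <= groups$half_width)
    },
    numeric(length(grid$thetas))
  ))
  if (any(rowSums(m) < 1)) {
    stop("empty neuronal group: half_width smaller than the grid spacing",
         call. = FALSE)
  }
  m
}

#' Group-averaged synaptic efficacy traces
#'
#' The instantaneous synaptic efficacy of group `G_i` is
#' `Jux_i(t) = (J/m_i) * sum_{theta in G_i} u(theta,t) x(theta,t)`; its
#' product with the peak connection strength is the activity-silent memory
#' trace of item i.  Also returns the pairwise contrasts
#' `dJux_ij(t) = Jux_j(t) - Jux_i(t)` for `j > i` (positive = later item
#' stronger).
#'
#' @param u_trace,x_trace matrices (time x neurons) of `u` and `x`.
#' @param times time stamps (one per row).
#' @param grid a [ring_grid()].
#' @param groups a [group_config()].
#' @param j_peak peak connection strength `J`.
#' @return list of tibbles: `jux` (t, group, jux) and `delta`
#'   (t, pair, delta_jux).
#' @export
group_efficacy <- function(u_trace, x_trace, times, grid, groups, j_peak) {
  stopifnot(nrow(u_trace) == length(times), all(dim(u_trace) == dim(x_trace)))
  mask <- group_mask(groups, grid)
  sizes <- rowSums(mask)
  ux <- u_trace * x_trace
  jux <- j_peak * sweep(ux %*% t(mask), 2, sizes, "/")
  ng <- length(groups$centers)
  jux_tbl <- tibble::tibble(
    t = rep(times, times = ng),
    group = rep(seq_len(ng), each = length(times)),
    jux = as.vector(jux)
  )
  pairs <- utils::combn(ng, 2, simplify = FALSE)
  delta_tbl <- purrr::map_dfr(pairs, function(pr) {
    tibble::tibble(
      t = times,
      pair = paste0(pr[1], pr[2]),
      delta_jux = jux[, pr[2]] - jux[, pr[1]]
    )
  })
  list(jux = jux_tbl, delta = delta_tbl)
}

#' Population-vector decoding of an orientation
#'
#' Estimates the encoded orientation from a rate profile as half the argument
#' of the rate-weighted resultant on doubled angles,
#' `0.5 * Arg(sum_k r_k exp(2i theta_k))` (doubling because orientation is
#' pi-periodic), wrapped to `[-pi/2, pi/2)`.
#'
#' @param rates nonnegative rate profile over the ring.
#' @param grid a [ring_grid()].
#' @param min_resultant decode only if the normalized resultant length
#'   exceeds this threshold; otherwise the profile is undecodable.
#' @return decoded orientation (radians), or an error for an all-zero or
#'   uniform profile.
#' @export
decode_population_vector <- function(rates, grid, min_resultant = 1e-6) {
  stopifnot(length(rates) == length(grid$thetas))
  total <- sum(rates)
  if (total <= 0) stop("undecodable rate profile: all rates zero",
                       call. = FALSE)
  z <- sum(rates * exp(2i * grid$thetas))
  if (Mod(z) / total < min_resultant) {
    stop("undecodable rate profile: resultant length ~ 0 (uniform profile)",
         call. = FALSE)
  }
  wrap_orientation(Arg(z) / 2)
}

#' Decode the recalled orientation from trial traces
#'
#' Averages the excitatory rate profile over the first half of the recall
#' window and applies [decode_population_vector()].  The response window is
#' the early part of the cue period because the network answers by igniting
#' a bump at the winning neuronal group within tens of milliseconds of cue
#' onset; that transient burst depletes the group's resources, and any
#' re-ignitions later in the cue period no longer reflect the efficacy
#' comparison that constitutes the memory read-out.  An undecodable profile
#' flags the trial as a guess (handled downstream by the mixture model).
#'
#' @param rate_trace matrix (time x neurons) of excitatory rates.
#' @param times time stamps for the rows.
#' @param recall_window length-2 numeric, the recall interval `(on, off)`.
#' @param grid a [ring_grid()].
#' @return list with `angle` (radians or NA) and `guess` (logical flag).
#' @export
recall_angle <- function(rate_trace, times, recall_window, grid) {
  stopifnot(length(recall_window) == 2L)
  if (diff(recall_window) <= 0) {
    stop("recall window must have positive length", call. = FALSE)
  }
  w1 <- mean(recall_window)  # first half of the recall window
  sel <- times >= recall_window[1] & times <= w1
  if (!any(sel)) stop("recall window outside recorded trace", call. = FALSE)
  profile <- colMeans(rate_trace[sel, , drop = FALSE])
  out <- tryCatch(
    list(angle = decode_population_vector(profile, grid), guess = FALSE),
    error = function(e) list(angle = NA_real_, guess = TRUE)
  )
  out
}
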