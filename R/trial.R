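#' Run one delay-recall trial
#'
#' Simulates the full protocol (sequential encoding, maintenance, cued
#' recall) from the resting state, records group-averaged rate and synaptic
#' efficacy traces, snapshots the STP state at each item's stimulus offset,
#' and decodes the recalled orientation from the time-averaged rate profile
#' over the first half of the recall window (the response forms as an
#' ignition burst within tens of milliseconds of cue onset; see
#' [recall_angle()]).
#'
#' An undecodable recall profile flags the trial as a guess; its error is
#' then drawn uniformly on `[-pi/2, pi/2)` (using the caller's R RNG
#' stream), is excluded from circular statistics downstream, and feeds the
#' uniform component of the response mixture.
#'
#' @param protocol a [task_protocol()].
#' @param params a [cann_params()].
#' @param seed integer seed for the integrator's RNG stream.
#' @param connectivity optional precomputed connection matrix.
#' @param group_half_width neuronal group half-width (radians).
#' @param group_stride steps between group-trace samples.
#' @param record also record full field traces at `record_stride` steps.
#' @param record_stride stride for full traces (if `record`).
#' @param ignition_threshold minimal peak of the window-averaged rate
#'   profile for the response to count as a retrieval.  The cue alone
#'   drives rates well below 1; a reactivated bump reaches tens to
#'   hundreds.  A profile that never ignites means the memory trace was too
#'   weak to retrieve, and the trial is scored as a uniform guess rather
#'   than read off the cue's own (trivially accurate) input profile.
#' @return object of class `swm_trial`: `result` (one-row tibble with cued
#'   item, target, recalled angle, wrapped error, guess flag),
#'   `group_trace` (tibble t/group/rate/jux), `offset_state` (tibble
#'   item/u0/x0), `maintain_start` (last-item offset time), `duration`, and
#'   optionally `trace`.
#' @export
run_trial <- function(protocol, params, seed = 1, connectivity = NULL,
                      group_half_width = 10 * pi / 180,
                      group_stride = 10L, record = FALSE,
                      record_stride = 20L, ignition_threshold = 5) {
  grid <- ring_grid(params$n_neurons)
  if (is.null(connectivity)) connectivity <- make_connectivity(params, grid)
  schedule <- build_schedule(protocol)
  groups <- group_config(protocol$item_angles, group_half_width)
  offsets <- item_offsets(protocol)
  total <- protocol_duration(protocol)
  if (protocol$t_recall <= 0) {
    stop("recall window must have positive length", call. = FALSE)
  }

  sim <- run_dynamics(
    initial_state(params), params, total, schedule = schedule,
    connectivity = connectivity, seed = seed,
    record_stride = if (record) record_stride else 0L,
    group_stride = group_stride, groups = groups,
    snapshot_times = offsets,
    decode_window = c(total - protocol$t_recall,
                      total - protocol$t_recall / 2)
  )

  target <- protocol$item_angles[protocol$cued_item]
  decoded <- if (max(sim$decode_profile) < ignition_threshold) {
    list(angle = NA_real_, guess = TRUE)   # retrieval failure
  } else {
    tryCatch(
      list(angle = decode_population_vector(sim$decode_profile, grid),
           guess = FALSE),
      error = function(e) list(angle = NA_real_, guess = TRUE)
    )
  }
  err <- if (decoded$guess) {
    stats::runif(1, -pi / 2, pi / 2)
  } else {
    wrap_orientation(decoded$angle - target)
  }

  nontargets <- protocol$item_angles[-protocol$cued_item]
  res <- tibble::tibble(
    m_items = length(protocol$item_angles),
    cued_item = protocol$cued_item,
    theta_true = target,
    theta_recalled = decoded$angle,
    error = err,
    guess = decoded$guess,
    nt1 = if (length(nontargets) >= 1) {
      wrap_orientation(nontargets[1] - target)
    } else NA_real_,
    nt2 = if (length(nontargets) >= 2) {
      wrap_orientation(nontargets[2] - target)
    } else NA_real_
  )

  structure(
    list(result = res, group_trace = sim$group_trace,
         offset_state = estimate_u0_x0(sim$snapshots, groups, grid),
         maintain_start = offsets[length(offsets)],
         duration = total, trace = sim$trace),
    class = "swm_trial"
  )
}

#' @export
print.swm_trial <- function(x, ...) {
  r <- x$result
  cat("<swm_trial>", r$m_items, "items, cued", r$cued_item, "\n")
  cat("  target", signif(r$theta_true, 4), "rad; recalled",
      signif(r$theta_recalled, 4), "rad; error",
      signif(r$error, 4), "rad", if (r$guess) "(guess)", "\n")
  invisible(x)
}

#' Offset STP state of a noise-free probe trial
#'
#' Runs a single deterministic (noise-free) trial of the given protocol and
#' returns the mean group-averaged `(u0, x0)` at item offsets.  Used to
#' parameterize the reduced theory with constants matched to the simulator.
#'
#' @param params a [cann_params()].
#' @param protocol a [task_protocol()]; defaults to a two-item protocol with
#'   the default timings and items 40 degrees apart.
#' @return list with `u0`, `x0` (scalars, averaged over items) and the
#'   per-item tibble `by_item`.
#' @export
probe_offset_state <- function(params, protocol = NULL) {
  if (is.null(protocol)) {
    protocol <- task_protocol(c(-0.2, -0.2 + 40 * pi / 180),
                              t_maintain = 0.2)
  }
  quiet <- params
  quiet$sigma0 <- 0
  protocol$encode_spec$noise_sigma <- 0
  protocol$recall_spec$noise_sigma <- 0
  tr <- run_trial(protocol, quiet, seed = 1)
  list(u0 = mean(tr$offset_state$u0), x0 = mean(tr$offset_state$x0),
       by_item = tr$offset_state)
}
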