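#' Calibrate the recurrent coupling
#'
#' Searches for a peak connection strength `J` such that (a) an encoding
#' stimulus evokes a clear activity bump, (b) the network falls back to
#' silence after stimulus offset (no persistent activity: the memory must be
#' activity-silent), and (c) a weak recall cue reactivates a bump centred on
#' the most facilitated neuronal group.  Condition (b) bounds `J` from
#' above (bisection on the largest silent `J`), condition (c) from below;
#' the accepted value is the largest `J` on a descending grid below the
#' silence bound for which all three conditions hold.
#'
#' All calibration probes run noise-free so the procedure is deterministic.
#'
#' @param params starting [cann_params()]; `j_peak` is replaced.
#' @param protocol probe protocol; defaults to a two-item protocol with the
#'   default timings.
#' @param j_range search interval for `J`.
#' @param encode_rate_min minimal peak rate during encoding for (a).
#' @param silence_frac maximal allowed rate at the end of maintenance, as a
#'   fraction of the encoding peak, for (b).
#' @param recall_tol maximal decoding error of the reactivated bump
#'   (radians) for (c).
#' @param n_bisect bisection iterations for the silence bound.
#' @return list with `params` (calibrated), `j_accepted`, `j_silence_max`,
#'   and a `log` tibble of the probes.
#' @export
calibrate_network <- function(params, protocol = NULL,
                              j_range = c(0.01, 2),
                              encode_rate_min = 10,
                              silence_frac = 0.01,
                              recall_tol = 20 * pi / 180,
                              n_bisect = 12) {
  if (is.null(protocol)) {
    # reactivation probed with a cue at a_encode/10, above the stochastic
    # ignition-threshold regime the task itself operates in
    protocol <- task_protocol(c(-0.2, wrap_orientation(-0.2 + 40 * pi / 180)),
                              t_maintain = 1.0,
                              recall_spec = stim_spec(4, 1,
                                                      noise_sigma = 0.5))
  }
  quiet <- params
  quiet$sigma0 <- 0
  protocol$encode_spec$noise_sigma <- 0
  protocol$recall_spec$noise_sigma <- 0

  probe <- function(j) {
    p <- quiet
    p$j_peak <- j
    p$j_floor <- -0.1 * j          # keep the surround floor proportional
    grid <- ring_grid(p$n_neurons)
    conn <- make_connectivity(p, grid)
    sched <- build_schedule(protocol)
    total <- protocol_duration(protocol)
    sim <- run_dynamics(initial_state(p), p, total, schedule = sched,
                        connectivity = conn, seed = 1, record_stride = 20L,
                        decode_window = c(total - protocol$t_recall / 2,
                                          total))
    tr <- sim$trace
    enc_end <- item_offsets(protocol)[length(protocol$item_angles)]
    maint_end <- enc_end + protocol$t_maintain
    peak_encode <- max(tr$r_e[tr$t <= enc_end])
    # silent window: end of the maintenance period, before the cue
    late <- tr$r_e[tr$t > maint_end - 0.2 * protocol$t_maintain &
                     tr$t <= maint_end]
    baseline <- firing_rate(p$i0, p$alpha)
    silent <- max(late) < silence_frac * peak_encode + 2 * baseline
    cue_ok <- FALSE
    decode_err <- NA_real_
    if (silent) {
      recall_peak <- max(tr$r_e[tr$t > maint_end])
      dec <- tryCatch(decode_population_vector(sim$decode_profile, grid),
                      error = function(e) NA_real_)
      if (!is.na(dec)) {
        decode_err <- abs(wrap_orientation(
          dec - protocol$item_angles[protocol$cued_item]))
        cue_ok <- recall_peak > 5 * baseline + 0.5 &&
          decode_err < recall_tol
      }
    }
    tibble::tibble(
      j = j, peak_encode = peak_encode, bump = peak_encode > encode_rate_min,
      silent = silent, cue_ok = cue_ok, decode_err = decode_err
    )
  }

  # bisection on the largest J that still returns to silence
  lo <- j_range[1]
  hi <- j_range[2]
  log <- list()
  p_lo <- probe(lo)
  log[[1]] <- p_lo
  if (!p_lo$silent) {
    stop("even the smallest J in j_range shows persistent activity",
         call. = FALSE)
  }
  for (i in seq_len(n_bisect)) {
    mid <- (lo + hi) / 2
    pm <- probe(mid)
    log[[length(log) + 1L]] <- pm
    if (pm$silent) lo <- mid else hi <- mid
  }
  j_silence_max <- lo

  accepted <- NA_real_
  for (frac in c(0.95, 0.9, 0.8, 0.7, 0.6, 0.5, 0.4, 0.3)) {
    pj <- probe(frac * j_silence_max)
    log[[length(log) + 1L]] <- pj
    if (pj$bump && pj$silent && pj$cue_ok) {
      accepted <- frac * j_silence_max
      break
    }
  }
  if (is.na(accepted)) {
    stop("no J in range satisfies bump + silence + cue reactivation; ",
         "adjust stimulus amplitudes or couplings", call. = FALSE)
  }
  out <- params
  out$j_peak <- accepted
  out$j_floor <- -0.1 * accepted
  list(params = out, j_accepted = accepted,
       j_silence_max = j_silence_max, log = dplyr::bind_rows(log))
}
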