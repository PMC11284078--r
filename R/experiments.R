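#' Experiment plan
#'
#' Scale and design of a delay-recall experiment.  At full scale the
#' paradigm uses 50 runs of 300 trials for two items and 500 for three,
#' with `T_maintain` over an 11-value grid from 0.1 to 10 s; the desk-scale
#' defaults (10 runs of 60 trials, a 5-point `T_maintain` set bracketing the
#' theoretical crossover) keep a complete experiment in the minutes range.
#'
#' @param m_items 2 or 3.
#' @param n_runs simulated "participants" (>= 2).
#' @param n_trials trials per run (>= 20).
#' @param t_maintain_set maintenance durations (s), or `NULL` to bracket the
#'   theoretical crossover with `tc * c(0.4, 0.7, 1, 1.5, 2.5)`.
#' @param t_encode,t_gap,t_recall protocol timings (s).  The gap defaults
#'   to 1 s for two items and 0.15 s for three: with three items every
#'   pairwise efficacy crossover is shifted earlier by one stride `t*`, so
#'   the first-vs-second crossover only falls inside the maintenance
#'   period when `tau_d * log((1-x0)/(1-exp(-t*/tau_f))) > t*`.
#' @param seed root seed; per-trial child seeds are derived by a counter so
#'   every trial is independently reproducible.
#' @param scale_factor divisor applied to `n_runs` and `n_trials` (>= 1).
#' @return object of class `experiment_plan`.
#' @export
experiment_plan <- function(m_items = 2L, n_runs = 10L, n_trials = 60L,
                            t_maintain_set = NULL, t_encode = 0.25,
                            t_gap = if (m_items == 2L) 1.0 else 0.15,
                            t_recall = 0.5, seed = 1L,
                            scale_factor = 1) {
  n_runs <- max(2L, as.integer(round(n_runs / scale_factor)))
  n_trials <- max(20L, as.integer(round(n_trials / scale_factor)))
  stopifnot(m_items %in% c(2L, 3L), n_runs >= 2L, n_trials >= 20L,
            t_encode > 0, t_gap >= 0, t_recall > 0, seed == round(seed))
  structure(
    list(m_items = as.integer(m_items), n_runs = n_runs,
         n_trials = n_trials, t_maintain_set = t_maintain_set,
         t_encode = t_encode, t_gap = t_gap, t_recall = t_recall,
         seed = as.integer(seed)),
    class = "experiment_plan"
  )
}

#' The full-scale 11-value maintenance grid
#' @return numeric vector of maintenance durations (s).
#' @export
t_maintain_full_grid <- function() {
  c(0.1, 0.2, 0.3, 0.4, 0.5, 1, 2, 4, 6, 8, 10)
}

# deterministic child seed per (root, run, trial); stays below 2^31
child_seed <- function(seed, run, trial) {
  (as.numeric(seed) * 97 + run * 10007 + trial * 101) %% 2147483629 + 1
}

protocol_for_trial <- function(plan, params, t_maintain, angles, cued) {
  task_protocol(
    angles, t_encode = plan$t_encode, t_gap = plan$t_gap,
    t_maintain = t_maintain, t_recall = plan$t_recall, cued_item = cued
  )
}

#' Run one maintenance-duration condition
#'
#' For each of `n_runs` runs, simulates `n_trials` trials with fresh item
#' orientations (cued item balanced across items within each run), fits the
#' response mixture per item per run, and computes circular variance and
#' kurtosis of the non-guess errors.  Also accumulates the trial-averaged
#' synaptic efficacy traces of all item groups.
#'
#' @param plan an [experiment_plan()].
#' @param params a [cann_params()].
#' @param t_maintain maintenance duration for this condition (s).
#' @param connectivity optional precomputed connection matrix.
#' @param group_stride steps between group-trace samples.
#' @return object of class `swm_condition`: `per_run` (run x item
#'   statistics), `stats` (per-item means), `contrasts` (pairwise Wilcoxon
#'   contrasts with significance categories), `responses` (per-trial
#'   tibble), `delta_jux` (trial-averaged relative efficacy over the
#'   maintenance period, time from last-item offset), `offset_state`
#'   (mean u0/x0 per item), `t_maintain`.
#' @export
run_condition <- function(plan, params, t_maintain, connectivity = NULL,
                          group_stride = 10L) {
  grid <- ring_grid(params$n_neurons)
  if (is.null(connectivity)) connectivity <- make_connectivity(params, grid)
  m <- plan$m_items

  responses <- vector("list", plan$n_runs * plan$n_trials)
  jux_sum <- NULL
  jux_sumsq <- NULL
  jux_t <- NULL
  maintain_start <- NULL
  u0_sum <- numeric(m)
  x0_sum <- numeric(m)
  n_tr <- 0L

  for (r in seq_len(plan$n_runs)) {
    for (k in seq_len(plan$n_trials)) {
      cs <- child_seed(plan$seed, r, k)
      set.seed(cs)
      angles <- draw_item_angles(m, grid_spacing = grid$spacing)
      cued <- (k - 1L) %% m + 1L
      pr <- protocol_for_trial(plan, params, t_maintain, angles, cued)
      tr <- tryCatch(
        run_trial(pr, params, seed = cs, connectivity = connectivity,
                  group_stride = group_stride),
        error = function(e) NULL
      )
      if (is.null(tr)) {  # failed trial: log and resample once
        cs2 <- child_seed(plan$seed, r, k + 100000L)
        set.seed(cs2)
        angles <- draw_item_angles(m, grid_spacing = grid$spacing)
        pr <- protocol_for_trial(plan, params, t_maintain, angles, cued)
        tr <- run_trial(pr, params, seed = cs2,
                        connectivity = connectivity,
                        group_stride = group_stride)
      }
      n_tr <- n_tr + 1L
      responses[[n_tr]] <- dplyr::mutate(tr$result, run = r, trial = k,
                                         .before = 1)
      # accumulate group efficacy contrasts on the shared time grid
      gt <- tr$group_trace
      jm <- matrix(gt$jux, ncol = m)
      if (is.null(jux_sum)) {
        jux_sum <- jm
        jux_sumsq <- jm^2
        jux_t <- gt$t[seq_len(nrow(jm))]
        maintain_start <- tr$maintain_start
      } else {
        jux_sum <- jux_sum + jm
        jux_sumsq <- jux_sumsq + jm^2
      }
      u0_sum <- u0_sum + tr$offset_state$u0
      x0_sum <- x0_sum + tr$offset_state$x0
    }
  }

  responses <- dplyr::bind_rows(responses[seq_len(n_tr)])

  per_run <- purrr::map_dfr(seq_len(plan$n_runs), function(r) {
    purrr::map_dfr(seq_len(m), function(i) {
      rows <- responses[responses$run == r & responses$cued_item == i, ]
      nt <- as.matrix(rows[, c("nt1", "nt2")])
      nt <- nt[, colSums(is.na(nt)) < nrow(nt), drop = FALSE]
      fit <- fit_response_mixture(rows$error, nt)
      good <- rows$error[!rows$guess]
      tibble::tibble(
        run = r, item = i, p = fit$p_target, kappa = fit$kappa,
        cv = circular_variance(good), ck = circular_kurtosis(good),
        n_trials = nrow(rows)
      )
    })
  })

  stats_tbl <- per_run |>
    dplyr::group_by(.data$item) |>
    dplyr::summarise(
      p = mean(.data$p), p_sd = stats::sd(.data$p),
      cv = mean(.data$cv), ck = mean(.data$ck),
      n_runs = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::mutate(t_maintain = t_maintain, .before = 1)

  pairs <- utils::combn(m, 2, simplify = FALSE)
  contrasts <- purrr::map_dfr(pairs, function(prr) {
    i <- prr[1]; j <- prr[2]
    wide <- function(col) {
      a <- per_run[per_run$item == i, ][[col]]
      b <- per_run[per_run$item == j, ][[col]]
      list(a = a, b = b)
    }
    pp <- wide("p")
    cc <- if (plan$n_runs >= 6) {
      compare_conditions(pp$a, pp$b)
    } else {  # too few runs for the rank test
      list(p_value = NA_real_, category = NA_character_,
           mean_diff = mean(pp$b - pp$a))
    }
    cvv <- wide("cv")
    ckk <- wide("ck")
    tibble::tibble(
      t_maintain = t_maintain, pair = paste0(i, j),
      d_p = cc$mean_diff, p_value = cc$p_value, significance = cc$category,
      d_cv = mean(cvv$a - cvv$b),   # positive = later item more precise
      d_ck = mean(ckk$b - ckk$a),
      per_run_d_p = list(pp$b - pp$a)
    )
  })

  jux_mean <- jux_sum / n_tr
  jux_sem <- sqrt(pmax(jux_sumsq / n_tr - jux_mean^2, 0) / n_tr)
  sel <- jux_t >= maintain_start - 1e-9 &
    jux_t <= maintain_start + t_maintain + 1e-9
  delta_jux <- purrr::map_dfr(pairs, function(prr) {
    tibble::tibble(
      t = jux_t[sel] - maintain_start,
      pair = paste0(prr[1], prr[2]),
      delta_jux = jux_mean[sel, prr[2]] - jux_mean[sel, prr[1]],
      sem = sqrt(jux_sem[sel, prr[1]]^2 + jux_sem[sel, prr[2]]^2)
    )
  })

  structure(
    list(per_run = per_run, stats = stats_tbl, contrasts = contrasts,
         responses = responses, delta_jux = delta_jux,
         offset_state = tibble::tibble(item = seq_len(m),
                                       u0 = u0_sum / n_tr,
                                       x0 = x0_sum / n_tr),
         t_maintain = t_maintain, plan = plan),
    class = "swm_condition"
  )
}

#' @export
print.swm_condition <- function(x, ...) {
  cat("<swm_condition> T_maintain =", x$t_maintain, "s,",
      x$plan$n_runs, "runs x", x$plan$n_trials, "trials\n")
  print(x$stats)
  invisible(x)
}

#' Run a full delay-recall experiment over maintenance durations
#'
#' Runs [run_condition()] at each maintenance duration, collects per-item
#' statistics and pairwise contrasts, locates the empirical performance
#' transition `T_c` (zero crossing of the mean `P` contrast over
#' `T_maintain`, also for the CV and CK contrasts), and the efficacy
#' crossover `T_c'(SIM)` from the trial-averaged `dJux(t)` of the
#' longest-maintenance condition.
#'
#' @param plan an [experiment_plan()].
#' @param params a [cann_params()].
#' @param verbose print per-condition progress to stderr.
#' @return object of class `swm_experiment`: `conditions` (list of
#'   `swm_condition`), `stats`, `contrasts`, `tc` (tibble: pair, estimator
#'   in p/cv/ck, tc), `tc_prime_sim` (tibble: pair, tc), `theory`
#'   (matched-parameter theory: u0, x0, `tc_exact`, `tc_simplified`),
#'   `plan`, `params`.
#' @export
run_experiment <- function(plan, params, verbose = FALSE) {
  grid <- ring_grid(params$n_neurons)
  connectivity <- make_connectivity(params, grid)

  # matched theory constants from a noise-free probe trial
  probe_protocol <- task_protocol(
    c(-0.2, wrap_orientation(-0.2 + 40 * pi / 180)),
    t_encode = plan$t_encode, t_gap = plan$t_gap, t_maintain = 0.2,
    t_recall = plan$t_recall
  )
  off <- probe_offset_state(params, probe_protocol)
  th <- theory_params(
    u0 = off$u0, x0 = off$x0, tau_f = params$tau_f, tau_d = params$tau_d,
    t_star = plan$t_encode + plan$t_gap, t_b = params$tau,
    j_peak = params$j_peak
  )
  tc_theo <- tc_exact(th)

  tms <- plan$t_maintain_set
  if (is.null(tms)) {
    if (plan$m_items == 3L) {
      tc3 <- tc_three_items(th)$tc
      if (any(is.na(tc3))) {
        stop("no three-item crossover inside the maintenance period for ",
             "these parameters; supply t_maintain_set explicitly",
             call. = FALSE)
      }
      # the early points sit well below the first crossover: encoding
      # interactions between three closely spaced items pull the simulated
      # 1-2 crossover below its reduced-theory value
      tms <- c(0.15 * tc3[1], 0.5 * tc3[1], mean(tc3), 1.3 * tc3[2],
               2 * tc3[2])
    } else {
      if (is.na(tc_theo)) {
        stop("no theoretical crossover for these parameters; supply ",
             "t_maintain_set explicitly", call. = FALSE)
      }
      tms <- tc_theo * c(0.4, 0.7, 1, 1.5, 2.5)
    }
  }
  tms <- sort(tms)

  conditions <- purrr::map(tms, function(tm) {
    if (verbose) message(sprintf("  T_maintain = %.3f s ...", tm))
    run_condition(plan, params, tm, connectivity = connectivity)
  })

  stats_tbl <- purrr::map_dfr(conditions, "stats")
  contrasts <- purrr::map_dfr(conditions, "contrasts")

  pairs <- unique(contrasts$pair)
  tc_tbl <- purrr::map_dfr(pairs, function(prr) {
    cc <- contrasts[contrasts$pair == prr, ]
    tc <- if (length(tms) >= 3) {
      c(empirical_tc(cc$t_maintain, cc$d_p)$tc,
        empirical_tc(cc$t_maintain, cc$d_cv)$tc,
        empirical_tc(cc$t_maintain, cc$d_ck)$tc)
    } else {
      rep(NA_real_, 3)   # too few durations to interpolate a crossing
    }
    tibble::tibble(pair = prr, estimator = c("p", "cv", "ck"), tc = tc)
  })

  last <- conditions[[length(conditions)]]
  tc_prime <- last$delta_jux |>
    dplyr::group_by(.data$pair) |>
    dplyr::summarise(tc = empirical_tc_prime(.data$t, .data$delta_jux),
                     .groups = "drop")

  theory <- tibble::tibble(
    u0 = off$u0, x0 = off$x0, t_star = th$t_star,
    tc_exact = tc_theo, tc_simplified = tc_simplified(th)
  )
  if (plan$m_items == 3L) {
    theory <- dplyr::bind_cols(
      theory,
      tidyr::pivot_wider(tc_three_items(th), names_from = "pair",
                         values_from = "tc", names_prefix = "tc_three_")
    )
  }

  structure(
    list(conditions = conditions, stats = stats_tbl, contrasts = contrasts,
         tc = tc_tbl, tc_prime_sim = tc_prime, theory = theory,
         plan = plan, params = params),
    class = "swm_experiment"
  )
}

#' @export
print.swm_experiment <- function(x, ...) {
  cat("<swm_experiment>", x$plan$m_items, "items,",
      length(x$conditions), "maintenance durations,",
      x$plan$n_runs, "runs x", x$plan$n_trials, "trials each\n")
  cat("  T_c (performance):\n")
  print(x$tc)
  cat("  T_c'(SIM):", signif(x$tc_prime_sim$tc, 4),
      "  T_c'(THEO):", signif(x$theory$tc_exact, 4), "s\n")
  invisible(x)
}

#' Tidy per-condition statistics of an experiment
#'
#' @param x a `swm_experiment`.
#' @param ... unused.
#' @return tibble: `t_maintain`, `item`, `p`, `p_sd`, `cv`, `ck`, `n_runs`.
#' @export
tidy.swm_experiment <- function(x, ...) {
  x$stats
}

#' @rdname tidy.swm_experiment
#' @return `glance`: one row with the transition summary.
#' @export
glance.swm_experiment <- function(x, ...) {
  tibble::tibble(
    m_items = x$plan$m_items,
    n_runs = x$plan$n_runs, n_trials = x$plan$n_trials,
    tc_p = x$tc$tc[x$tc$estimator == "p"][1],
    tc_prime_sim = x$tc_prime_sim$tc[1],
    tc_theo = x$theory$tc_exact
  )
}

#' Run the three-item experiment
#'
#' [run_experiment()] with `m_items = 3`, reporting both pairwise contrasts
#' (first vs second, second vs third) and their critical moments; by the
#' shift relation the crossovers satisfy `Tc12 < Tc23` with
#' `Tc23 - Tc12 = t*`.
#'
#' @param plan an [experiment_plan()] (with `m_items = 3`); trial counts
#'   default to the three-item paradigm.
#' @param params a [cann_params()].
#' @param verbose print progress.
#' @return a `swm_experiment` (pairs "12", "13", "23" in contrasts).
#' @export
run_three_item_experiment <- function(plan, params, verbose = FALSE) {
  stopifnot(plan$m_items == 3L)
  run_experiment(plan, params, verbose = verbose)
}

#' Parameter sweep over STP constants and the inter-item gap
#'
#' For each point of a grid over two of `tau_f`, `tau_d`, `t_gap`, runs a
#' (scaled) experiment and records the empirical transition `T_c` under all
#' three statistics, the simulated efficacy crossover `T_c'(SIM)`, and the
#' matched closed-form predictions.  Axes must stay within the studied
#' ranges: `tau_f` in \[2, 8\] s, `tau_d` in \[0.1, 0.4\] s, `t_gap` in
#' \[0, 2\] s.
#'
#' @param plan an [experiment_plan()] giving the per-point scale.
#' @param params baseline [cann_params()].
#' @param axes named list of one to three axis grids, e.g.
#'   `list(tau_f = seq(2, 8, length.out = 5), t_gap = c(0, 1, 2))`.
#' @param verbose print progress.
#' @return tibble (class `swm_sweep`) with one row per grid point:
#'   the axis values, `tc_p`, `tc_cv`, `tc_ck`, `tc_prime_sim`,
#'   `tc_exact`, `tc_simplified` (NA marks an out-of-range crossing).
#' @export
run_sweep <- function(plan, params, axes, verbose = FALSE) {
  ranges <- list(tau_f = c(2, 8), tau_d = c(0.1, 0.4), t_gap = c(0, 2))
  stopifnot(length(axes) >= 1, all(names(axes) %in% names(ranges)))
  for (nm in names(axes)) {
    if (any(axes[[nm]] < ranges[[nm]][1] | axes[[nm]] > ranges[[nm]][2])) {
      stop("axis ", nm, " outside the studied range [",
           ranges[[nm]][1], ", ", ranges[[nm]][2], "] s", call. = FALSE)
    }
  }
  grid_tbl <- tidyr::expand_grid(!!!axes)
  rows <- purrr::map_dfr(seq_len(nrow(grid_tbl)), function(i) {
    pt <- as.list(grid_tbl[i, ])
    p_i <- params
    plan_i <- plan
    if (!is.null(pt$tau_f)) p_i$tau_f <- pt$tau_f
    if (!is.null(pt$tau_d)) p_i$tau_d <- pt$tau_d
    if (!is.null(pt$t_gap)) plan_i$t_gap <- pt$t_gap
    if (verbose) {
      message("sweep point ", i, "/", nrow(grid_tbl), ": ",
              paste(names(pt), signif(unlist(pt), 3), sep = "=",
                    collapse = ", "))
    }
    ex <- run_experiment(plan_i, p_i, verbose = FALSE)
    tc <- ex$tc[ex$tc$pair == "12", ]
    dplyr::bind_cols(
      grid_tbl[i, ],
      tibble::tibble(
        tc_p = tc$tc[tc$estimator == "p"],
        tc_cv = tc$tc[tc$estimator == "cv"],
        tc_ck = tc$tc[tc$estimator == "ck"],
        tc_prime_sim = ex$tc_prime_sim$tc[ex$tc_prime_sim$pair == "12"],
        tc_exact = ex$theory$tc_exact,
        tc_simplified = ex$theory$tc_simplified
      )
    )
  })
  class(rows) <- c("swm_sweep", class(rows))
  rows
}
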