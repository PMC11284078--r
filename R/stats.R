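#' Significance category for a per-run performance contrast
#'
#' Two-sided paired Wilcoxon signed-rank test on the per-run differences of
#' a recall statistic between two items (proportions are bounded, so a rank
#' test is used rather than a t-test).  The p value is mapped to the
#' conventional categories: `n.s.` (p > 0.05), `*` (0.01 < p < 0.05),
#' `**` (0.001 < p < 0.01), `***` (p < 0.001).
#'
#' @param p_a,p_b per-run statistics for the two items (equal length >= 6).
#' @return list with `p_value`, `category`, and the mean difference
#'   `mean_diff` (`p_b - p_a`).
#' @export
compare_conditions <- function(p_a, p_b) {
  stopifnot(length(p_a) == length(p_b), length(p_a) >= 6)
  d <- p_b - p_a
  if (all(d == 0)) {
    return(list(p_value = 1, category = "n.s.", mean_diff = 0))
  }
  p <- suppressWarnings(
    stats::wilcox.test(p_b, p_a, paired = TRUE, exact = FALSE)$p.value
  )
  list(p_value = p, category = significance_category(p), mean_diff = mean(d))
}

significance_category <- function(p) {
  if (is.na(p) || p > 0.05) "n.s."
  else if (p > 0.01) "*"
  else if (p > 0.001) "**"
  else "***"
}

# first linear-interpolation zero crossing of y(x); NA when no sign change
first_zero_crossing <- function(x, y) {
  stopifnot(length(x) == length(y), !is.unsorted(x))
  ok <- is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2) return(NA_real_)
  if (any(y == 0)) return(x[which(y == 0)[1]])
  s <- sign(y)
  flip <- which(s[-1] != s[-length(s)])
  if (length(flip) == 0) return(NA_real_)
  i <- flip[1]
  x[i] + (x[i + 1] - x[i]) * (0 - y[i]) / (y[i + 1] - y[i])
}

#' Empirical performance transition time
#'
#' The maintenance duration at which a recall-performance contrast (for
#' example mean `P_2 - P_1`) crosses zero, located by linear interpolation
#' between the bracketing samples of the `T_maintain` grid.  Optionally
#' bootstraps a confidence interval over runs.
#'
#' @param t_maintain sampled maintenance durations (s), increasing, >= 3.
#' @param contrast mean contrast at each duration (later minus earlier
#'   item).
#' @param runs optional matrix (`n_runs x length(t_maintain)`) of per-run
#'   contrasts for a bootstrap CI.
#' @param n_boot bootstrap replicates.
#' @return list with `tc` (s; `NA` when the curve does not change sign in
#'   range) and, when `runs` is given, `ci` (2.5/97.5 percentiles).
#' @export
empirical_tc <- function(t_maintain, contrast, runs = NULL, n_boot = 200) {
  stopifnot(length(t_maintain) >= 3)
  tc <- first_zero_crossing(t_maintain, contrast)
  out <- list(tc = tc)
  if (!is.null(runs) && !is.na(tc)) {
    boots <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(nrow(runs), replace = TRUE)
      first_zero_crossing(t_maintain, colMeans(runs[idx, , drop = FALSE]))
    }, numeric(1))
    out$ci <- stats::quantile(boots, c(0.025, 0.975), na.rm = TRUE)
  }
  out
}

#' Empirical efficacy crossover time
#'
#' First zero crossing (linear interpolation) of the trial-averaged relative
#' synaptic efficacy `dJux(t)` over the maintenance period, with time
#' measured from last-item offset.  This is the simulated counterpart of
#' [tc_exact()].
#'
#' @param t times since last-item offset (s), increasing.
#' @param delta_jux trial-averaged `dJux` at those times.
#' @return crossing time (s), or `NA_real_` when the trace does not change
#'   sign in range.
#' @export
empirical_tc_prime <- function(t, delta_jux) {
  first_zero_crossing(t, delta_jux)
}
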