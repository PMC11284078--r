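#' Write a run manifest
#'
#' Every experiment directory carries a JSON manifest sufficient to re-run
#' it bit-identically: the network parameters, the experiment plan
#' (including the resolved maintenance grid), the root seed (child seeds are
#' derived deterministically from it), and the package version.
#'
#' @param plan an [experiment_plan()].
#' @param params a [cann_params()].
#' @param path output file path.
#' @param t_maintain_set the resolved maintenance grid (s), if the plan left
#'   it `NULL`.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(plan, params, path,
                           t_maintain_set = plan$t_maintain_set) {
  validate_cann_params(params)
  if (is.null(plan$seed)) stop("plan has no seed", call. = FALSE)
  manifest <- list(
    package = "swmcann",
    version = as.character(utils::packageVersion("swmcann")),
    seed = plan$seed,
    child_seed_rule = "(seed*97 + run*10007 + trial*101) mod (2^31-19) + 1",
    plan = unclass(plan)[c("m_items", "n_runs", "n_trials", "t_encode",
                           "t_gap", "t_recall")],
    t_maintain_set = t_maintain_set,
    params = unclass(params)
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a run manifest back into plan and parameters
#'
#' @param path manifest file.
#' @return list with `plan`, `params`, `t_maintain_set`.
#' @export
read_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(m$seed)) stop("manifest is missing the seed", call. = FALSE)
  plan <- do.call(experiment_plan, c(
    m$plan, list(seed = m$seed, t_maintain_set = m$t_maintain_set)
  ))
  params <- do.call(cann_params, m$params)
  list(plan = plan, params = params, t_maintain_set = m$t_maintain_set)
}

fmt6 <- function(x) {
  if (is.numeric(x)) signif(x, 6) else x
}

#' Write experiment outputs as delimited text
#'
#' Writes `per_trial.csv` (one row per trial), `per_condition.csv` (per
#' maintenance duration and item, with the significance category of the
#' adjacent-item contrast), `contrasts.csv`, `delta_jux.csv`, and
#' `manifest.json` into `dir`.  Floats are written at 6 significant digits.
#'
#' @param experiment a `swm_experiment` from [run_experiment()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(experiment, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ex <- experiment

  per_trial <- purrr::map_dfr(ex$conditions, function(cond) {
    dplyr::mutate(cond$responses, t_maintain = cond$t_maintain, .before = 1)
  }) |>
    dplyr::select("t_maintain", run_id = "run", trial_id = "trial",
                  "m_items", "cued_item", "theta_true", "theta_recalled",
                  "error", "guess")
  write_csv6(per_trial, file.path(dir, "per_trial.csv"))

  sig <- ex$contrasts |>
    dplyr::mutate(item = as.integer(substr(.data$pair, 1, 1))) |>
    dplyr::select("t_maintain", "item", "significance")
  per_condition <- ex$stats |>
    dplyr::left_join(sig, by = c("t_maintain", "item")) |>
    dplyr::select("t_maintain", "item", p_target = "p", "cv", "ck",
                  "n_runs", "significance")
  write_csv6(per_condition, file.path(dir, "per_condition.csv"))

  write_csv6(dplyr::select(ex$contrasts, -"per_run_d_p"),
             file.path(dir, "contrasts.csv"))

  delta <- purrr::map_dfr(ex$conditions, function(cond) {
    dplyr::mutate(cond$delta_jux, t_maintain = cond$t_maintain, .before = 1)
  })
  write_csv6(delta, file.path(dir, "delta_jux.csv"))

  write_manifest(ex$plan, ex$params, file.path(dir, "manifest.json"),
                 t_maintain_set = purrr::map_dbl(ex$conditions,
                                                "t_maintain"))
  invisible(dir)
}

write_csv6 <- function(df, path) {
  df <- dplyr::mutate(df, dplyr::across(dplyr::where(is.numeric), fmt6))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Re-run an experiment from its manifest
#'
#' Reconstructs the plan and parameters from a manifest and re-executes the
#' experiment; with the same package version this reproduces the output
#' CSVs byte-identically.
#'
#' @param manifest_path path to a `manifest.json`.
#' @param out_dir where to write the reproduced outputs (see
#'   [write_experiment()]); `NULL` skips writing.
#' @return the `swm_experiment`.
#' @export
rerun_from_manifest <- function(manifest_path, out_dir = NULL) {
  m <- read_manifest(manifest_path)
  ex <- run_experiment(m$plan, m$params)
  if (!is.null(out_dir)) write_experiment(ex, out_dir)
  ex
}
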