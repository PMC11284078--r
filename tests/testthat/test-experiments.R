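test_that("experiment plans validate and scale", {
  plan <- experiment_plan(n_runs = 10, n_trials = 60, scale_factor = 2)
  expect_equal(plan$n_runs, 5L)
  expect_equal(plan$n_trials, 30L)
  expect_error(experiment_plan(m_items = 4), "m_items")
  expect_error(experiment_plan(t_encode = 0))
  expect_equal(length(t_maintain_full_grid()), 11)
  expect_equal(t_maintain_full_grid()[6], 1)
})

test_that("child seeds are deterministic, distinct, and below 2^31", {
  s <- outer(1:50, 1:500, function(r, k) swmcann:::child_seed(7, r, k))
  expect_equal(length(unique(as.vector(s))), 50 * 500)
  expect_true(all(s > 0 & s < 2^31))
  expect_identical(swmcann:::child_seed(7, 3, 9),
                   swmcann:::child_seed(7, 3, 9))
})

test_that("manifests round-trip the full configuration", {
  plan <- experiment_plan(seed = 123, t_maintain_set = c(0.2, 0.6))
  params <- cann_params(tau_f = 3)
  path <- withr::local_tempfile(fileext = ".json")
  write_manifest(plan, params, path)
  back <- read_manifest(path)
  expect_equal(unclass(back$params), unclass(params))
  expect_equal(back$plan$seed, 123L)
  expect_equal(back$plan$n_trials, plan$n_trials)
  expect_equal(back$t_maintain_set, c(0.2, 0.6))

  # a manifest without a seed is invalid
  m <- jsonlite::read_json(path)
  m$seed <- NULL
  path2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(m, path2, auto_unbox = TRUE)
  expect_error(read_manifest(path2), "seed")
})

test_that("plans differing only in seed draw different item angles", {
  grid <- ring_grid(128)
  set.seed(swmcann:::child_seed(1, 1, 1))
  a <- draw_item_angles(2L)
  set.seed(swmcann:::child_seed(2, 1, 1))
  b <- draw_item_angles(2L)
  expect_false(identical(a, b))
})

test_that("a full experiment reruns byte-identically from its manifest", {
  plan <- experiment_plan(n_runs = 2L, n_trials = 40L, seed = 99L,
                          t_maintain_set = c(0.15, 0.6))
  params <- cann_params()
  ex <- run_experiment(plan, params)
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  write_experiment(ex, dir1)
  rerun_from_manifest(file.path(dir1, "manifest.json"), dir2)
  for (f in c("per_trial.csv", "per_condition.csv", "contrasts.csv",
              "delta_jux.csv")) {
    expect_identical(readBin(file.path(dir1, f), "raw", 1e7),
                     readBin(file.path(dir2, f), "raw", 1e7),
                     label = f)
  }

  # result object supports the tidy/plot surface
  expect_s3_class(tidy(ex), "tbl_df")
  expect_equal(nrow(glance(ex)), 1)
  expect_s3_class(autoplot(ex), "ggplot")
  expect_s3_class(plot_delta_jux(ex$conditions[[1]]), "ggplot")
  tr <- run_trial(task_protocol(c(-0.2, 0.3), t_maintain = 0.2),
                  cann_params(), seed = 1, record = TRUE)
  expect_s3_class(plot_trial(tr), "ggplot")
})

test_that("a scaled condition run emits complete statistics", {
  plan <- experiment_plan(n_runs = 2L, n_trials = 40L, seed = 3L)
  params <- cann_params()
  cond <- run_condition(plan, params, t_maintain = 0.3)
  expect_s3_class(cond, "swm_condition")
  expect_equal(nrow(cond$stats), 2)
  expect_true(all(cond$stats$p >= 0 & cond$stats$p <= 1))
  expect_true(all(cond$stats$cv >= 0 & cond$stats$cv <= 1))
  expect_equal(nrow(cond$per_run), 4)
  expect_equal(nrow(cond$responses), 80)
  expect_equal(sort(unique(cond$responses$cued_item)), 1:2)
  # cue balancing within each run
  expect_equal(sum(cond$responses$cued_item == 1), 40)
  # the relative efficacy trace covers the maintenance window from offset
  dj <- cond$delta_jux
  expect_equal(min(dj$t), 0)
  expect_equal(max(dj$t), 0.3, tolerance = 0.02)
  expect_true(all(is.finite(dj$delta_jux)))
  # offset state is physical
  expect_true(all(cond$offset_state$u0 > 0 & cond$offset_state$u0 <= 1))
  expect_true(all(cond$offset_state$x0 >= 0 & cond$offset_state$x0 < 1))
})

test_that("sweeps validate their axes and emit complete rows", {
  plan <- experiment_plan(n_runs = 2L, n_trials = 40L, seed = 5L)
  params <- cann_params()
  expect_error(
    run_sweep(plan, params, list(tau_f = c(1, 4))),
    "outside the studied range"
  )
  # theory-side columns of a sweep grid are monotone in tau_d
  g <- theory_grid(tau_f = 4, tau_d = seq(0.1, 0.4, length.out = 5),
                   t_gap = 1)
  expect_true(all(diff(g$tc_exact) > 0))

  # 2x2 smoke sweep emits four complete rows
  plan$t_maintain_set <- c(0.15, 0.35, 0.7)
  sw <- run_sweep(plan, params,
                  list(tau_d = c(0.25, 0.35), t_gap = c(0.75, 1.25)))
  expect_equal(nrow(sw), 4)
  expect_true(all(c("tc_p", "tc_cv", "tc_ck", "tc_prime_sim", "tc_exact",
                    "tc_simplified") %in% names(sw)))
  expect_true(all(is.finite(sw$tc_exact)))
  # theory column increases with tau_d at fixed gap
  for (tg in unique(sw$t_gap)) {
    sub <- sw[sw$t_gap == tg, ]
    expect_gt(sub$tc_exact[sub$tau_d == 0.35],
              sub$tc_exact[sub$tau_d == 0.25])
  }
})
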