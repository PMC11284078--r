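test_that("synthetic responses follow the requested mixture", {
  set.seed(1)
  # all mass on the target with huge concentration -> responses at target
  r <- generate_synthetic_responses(c(0.3, -0.5), kappa = 1e4,
                                    weights = c(1, 0, 0), n_trials = 200)
  expect_true(all(abs(wrap_orientation(r$response - 0.3)) < 0.05))

  # pure uniform guessing
  u <- generate_synthetic_responses(c(0.3, -0.5), kappa = 8,
                                    weights = c(0, 0, 1), n_trials = 5000)
  ks <- suppressWarnings(stats::ks.test(u$response, "punif", -pi / 2, pi / 2))
  expect_gt(ks$p.value, 0.01)

  expect_error(
    generate_synthetic_responses(0.1, 5, c(0.5, 0.2), 10),
    "sum to 1"
  )
})

test_that("mixture fit recovers generating parameters (round trip)", {
  set.seed(42)
  target <- 0.2
  nontarget <- -0.4
  r <- generate_synthetic_responses(c(target, nontarget), kappa = 8,
                                    weights = c(0.7, 0.2, 0.1),
                                    n_trials = 2000)
  errors <- wrap_orientation(r$response - target)
  nt <- matrix(wrap_orientation(nontarget - target), 2000, 1)
  fit <- fit_response_mixture(errors, nt)
  expect_true(fit$converged)
  expect_lt(abs(fit$weights[["w_target"]] - 0.7), 0.05)
  expect_lt(abs(fit$weights[["w_nontarget"]] - 0.2), 0.05)
  expect_lt(abs(fit$weights[["w_uniform"]] - 0.1), 0.05)
  expect_equal(fit$kappa, 8, tolerance = 0.2 * 8)
  # posteriors are proper probabilities
  expect_equal(rowSums(as.matrix(fit$posterior)), rep(1, 2000),
               tolerance = 1e-12)
  expect_true(fit$p_target >= 0 && fit$p_target <= 1)
})

test_that("normalized target probability has the expected limit cases", {
  set.seed(11)
  # all responses exactly on target, far non-target -> P near 1
  errors <- rnorm(200, 0, 0.01)
  nt <- matrix(40 * pi / 180, 200, 1)
  expect_gt(normalized_target_probability(errors, nt), 0.95)

  # uniform responses -> the uniform component dominates and P is near the
  # uniform-dominated chance level (simulated frozen reference)
  u <- runif(5000, -pi / 2, pi / 2)
  p_unif <- normalized_target_probability(u, matrix(40 * pi / 180, 5000, 1))
  expect_lt(p_unif, 0.2)

  # responses split 50/50 exactly on the two item angles -> P ~ 0.5
  delta <- 30 * pi / 180
  errors <- rep(c(0, delta), each = 100) + rnorm(200, 0, 0.01)
  nt <- matrix(delta, 200, 1)
  expect_equal(normalized_target_probability(errors, nt), 0.5,
               tolerance = 0.05)
})

test_that("fits require at least 20 trials and expose tidy summaries", {
  expect_error(fit_response_mixture(rnorm(10, 0, 0.1)), "at least 20")
  set.seed(3)
  fit <- fit_response_mixture(rnorm(50, 0, 0.2),
                              matrix(0.6, 50, 1))
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$component,
               c("w_target", "w_nontarget", "w_uniform"))
  expect_equal(sum(td$weight), 1, tolerance = 1e-6)
  gl <- glance(fit)
  expect_equal(gl$n, 50)
  expect_true(is.finite(gl$loglik))
})
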