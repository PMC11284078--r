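test_that("reference R step and compiled integrator agree (noise-free)", {
  p <- tiny_params(n = 48L)
  g <- ring_grid(48)
  w <- make_connectivity(p, g)
  st <- initial_state(p)
  st$h_e <- rnorm(48, -2, 1)
  st$u <- runif(48, 0, 0.8)
  st$x <- runif(48, 0.2, 1)
  ext <- stimulus_profile(stim_spec(10, 4, 0.2), g)
  sched <- tibble::tibble(t_start = 0, t_end = p$dt, phase = "encode",
                          item = 1L, amplitude = 10, sharpness = 4,
                          center = 0.2, noise_sigma = 0)
  ref <- network_step(st, ext, p, w)
  cpp <- run_dynamics(st, p, p$dt, schedule = sched, connectivity = w)$state
  expect_equal(cpp$h_e, ref$h_e, tolerance = 1e-12)
  expect_equal(cpp$h_i, ref$h_i, tolerance = 1e-12)
  expect_equal(cpp$u, ref$u, tolerance = 1e-12)
  expect_equal(cpp$x, ref$x, tolerance = 1e-12)
})

test_that("the silent network sits at a stable fixed point", {
  p <- tiny_params(n = 32L)
  a <- run_dynamics(initial_state(p), p, 30)$state
  b <- run_dynamics(a, p, 1)$state
  expect_lt(max(abs(b$h_e - a$h_e)), 1e-5)
  expect_lt(max(abs(b$u - a$u)), 1e-5)
  expect_lt(max(abs(b$x - a$x)), 1e-5)
  # and the fixed-point rates are essentially silent
  expect_lt(max(firing_rate(a$h_e, p$alpha)), 0.05)
})

test_that("STP relaxes linearly when the network cannot fire", {
  # i0 so negative that r_E is numerically zero: Eq-4 dynamics reduce to
  # pure exponential relaxation
  p <- tiny_params(n = 16L, i0 = -200, tau_f = 0.05, tau_d = 0.01)
  st <- initial_state(p)
  st$h_e <- rep(-200, 16)
  st$u <- rep(0.5, 16)
  st$x <- rep(0.5, 16)
  out <- run_dynamics(st, p, 5 * p$tau_f)$state
  expect_lt(max(out$u), 0.01 * 0.5)
  expect_equal(out$x, rep(1, 16), tolerance = 1e-3)
  closed <- stp_relax(0.5, 0.5, 5 * p$tau_f, p$tau_f, p$tau_d)
  expect_lt(abs(mean(out$u) - closed$u), 1e-3)
})

test_that("a sustained bump input facilitates u and depletes x locally", {
  p <- cann_params(sigma0 = 0)
  g <- ring_grid(p$n_neurons)
  sched <- tibble::tibble(t_start = 0, t_end = 0.25, phase = "encode",
                          item = 1L, amplitude = 40, sharpness = 8,
                          center = 0, noise_sigma = 0)
  out <- run_dynamics(initial_state(p), p, 0.25, schedule = sched)$state
  center <- which.min(abs(g$thetas))
  far <- which.min(abs(g$thetas - 1.2))
  expect_gt(out$u[center], 0.5)
  expect_lt(out$x[center], 0.5)
  expect_lt(out$u[far], 0.1)
  expect_gt(out$x[far], 0.9)
})

test_that("u and x stay in [0,1] under randomized strong inputs", {
  p <- tiny_params(n = 32L, sigma0 = 0.5)
  for (seed in 1:5) {
    set.seed(seed)
    sched <- tibble::tibble(
      t_start = c(0, 0.05), t_end = c(0.1, 0.15), phase = "encode",
      item = 1L, amplitude = runif(2, 0, 80),
      sharpness = runif(2, 1, 8), center = runif(2, -1.5, 1.5),
      noise_sigma = runif(2, 0, 2)
    )
    out <- run_dynamics(initial_state(p), p, 0.2, schedule = sched,
                        seed = seed, record_stride = 10L)
    expect_true(all(out$trace$u >= 0 & out$trace$u <= 1))
    expect_true(all(out$trace$x >= 0 & out$trace$x <= 1))
    expect_true(all(is.finite(out$trace$h_e)))
  }
})

test_that("equal seeds reproduce traces exactly; duration 0 is a no-op", {
  p <- tiny_params(n = 32L, sigma0 = 0.3)
  sched <- tibble::tibble(t_start = 0, t_end = 0.05, phase = "encode",
                          item = 1L, amplitude = 20, sharpness = 4,
                          center = 0, noise_sigma = 0.5)
  a <- run_dynamics(initial_state(p), p, 0.1, schedule = sched, seed = 42,
                    record_stride = 5L)
  b <- run_dynamics(initial_state(p), p, 0.1, schedule = sched, seed = 42,
                    record_stride = 5L)
  expect_identical(a$trace, b$trace)
  d <- run_dynamics(initial_state(p), p, 0.1, schedule = sched, seed = 43,
                    record_stride = 5L)
  expect_false(identical(a$trace$h_e, d$trace$h_e))

  z <- run_dynamics(initial_state(p), p, 0)
  expect_equal(z$state, initial_state(p))
})

test_that("recording stride bookkeeping matches floor(duration/stride/dt)+1", {
  p <- tiny_params(n = 16L)
  dur <- 0.05
  out <- run_dynamics(initial_state(p), p, dur, record_stride = 10L)
  n_expected <- floor(dur / (10 * p$dt)) + 1
  expect_equal(length(unique(out$trace$t)), n_expected)
})

test_that("rotating the stimulus rotates the noise-free response exactly", {
  p <- tiny_params(n = 32L)
  g <- ring_grid(32)
  run_at <- function(center) {
    sched <- tibble::tibble(t_start = 0, t_end = 0.1, phase = "encode",
                            item = 1L, amplitude = 30, sharpness = 3,
                            center = center, noise_sigma = 0)
    firing_rate(run_dynamics(initial_state(p), p, 0.1,
                             schedule = sched)$state$h_e, p$alpha)
  }
  k <- 5L
  r0 <- run_at(g$thetas[1])
  rk <- run_at(g$thetas[1 + k])
  expect_equal(rk, r0[((seq_len(32) - 1L - k) %% 32L) + 1L],
               tolerance = 1e-10)
})

test_that("activity decays to silence after stimulus offset (calibrated)", {
  p <- cann_params(sigma0 = 0)
  pr <- quiet_protocol(t_maintain = 1.0)
  sim <- run_dynamics(initial_state(p), p,
                      swmcann:::protocol_duration(pr) - pr$t_recall,
                      schedule = build_schedule(pr), record_stride = 20L)
  tr <- sim$trace
  peak <- max(tr$r_e[tr$t <= 1.5])
  late <- max(tr$r_e[tr$t > 2.3])     # end of the maintenance period
  expect_gt(peak, 10)
  expect_lt(late, 0.01 * peak)
})

test_that("global inhibition leaves one dominant bump for equal inputs", {
  p <- cann_params()   # background noise on to break symmetry
  g <- ring_grid(p$n_neurons)
  sched <- tibble::tibble(
    t_start = 0, t_end = 0.6, phase = "encode", item = 1L,
    amplitude = 8, sharpness = 8, center = c(-0.6, 0.6), noise_sigma = 0.3
  )
  out <- run_dynamics(initial_state(p), p, 0.6, schedule = sched, seed = 7)
  r <- firing_rate(out$state$h_e, p$alpha)
  peak1 <- max(r[abs(g$thetas + 0.6) < 0.2])
  peak2 <- max(r[abs(g$thetas - 0.6) < 0.2])
  expect_lt(min(peak1, peak2) / max(peak1, peak2), 0.5)
})

test_that("halving dt changes the offset efficacy by < 1%", {
  p <- cann_params(sigma0 = 0)
  run_with_dt <- function(dt) {
    q <- p
    q$dt <- dt
    sched <- tibble::tibble(t_start = 0, t_end = 0.25, phase = "encode",
                            item = 1L, amplitude = 40, sharpness = 8,
                            center = 0, noise_sigma = 0)
    st <- run_dynamics(initial_state(q), q, 0.25, schedule = sched)$state
    groups <- group_config(0)
    mask <- swmcann:::group_mask(groups, ring_grid(p$n_neurons))[1, ] > 0
    p$j_peak * mean(st$u[mask] * st$x[mask])
  }
  j1 <- run_with_dt(p$dt)
  j2 <- run_with_dt(p$dt / 2)
  expect_lt(abs(j1 - j2) / abs(j2), 0.01)
})

test_that("a diverging integration reports time and magnitude", {
  p <- tiny_params(n = 16L)
  p$j_peak <- 1e8
  p$j_floor <- -1e7
  sched <- tibble::tibble(t_start = 0, t_end = 0.3, phase = "encode",
                          item = 1L, amplitude = 50, sharpness = 2,
                          center = 0, noise_sigma = 0)
  expect_error(
    run_dynamics(initial_state(p), p, 0.3, schedule = sched,
                 connectivity = make_connectivity(p)),
    "blew up at t"
  )
})
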