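test_that("silent STP relaxation matches its closed form and an integrator", {
  expect_equal(stp_relax(0.8, 0.2, 0, 4, 0.3), list(u = 0.8, x = 0.2))
  far <- stp_relax(0.8, 0.2, 1e6, 4, 0.3)
  expect_equal(far$u, 0)
  expect_equal(far$x, 1)
  expect_equal(stp_relax(0.8, 0.2, 4, 4, 0.3)$u, 0.8 / exp(1),
               tolerance = 1e-12)
  expect_error(stp_relax(0.5, 0.5, -1, 4, 0.3), "nonnegative")

  # independent oracle: explicit Euler integration of the r = 0 dynamics
  # at dt = 1 ms
  euler_relax <- function(u0, x0, t_end, tau_f, tau_d, dt = 1e-3) {
    u <- u0
    x <- x0
    for (i in seq_len(round(t_end / dt))) {
      u <- u + dt * (-u / tau_f)
      x <- x + dt * ((1 - x) / tau_d)
    }
    list(u = u, x = x)
  }
  set.seed(8)
  for (i in 1:20) {
    u0 <- runif(1, 0.1, 1)
    x0 <- runif(1, 0, 1)
    tau_f <- runif(1, 2, 8)
    tau_d <- runif(1, 0.1, 0.4)
    for (t_end in c(0.25, 1, 5) * tau_f) {
      num <- euler_relax(u0, x0, t_end, tau_f, tau_d)
      cf <- stp_relax(u0, x0, t_end, tau_f, tau_d)
      expect_lt(abs(num$u - cf$u), 1e-3)
      expect_lt(abs(num$x - cf$x), 1e-3)
    }
  }
})

test_that("group efficacy trace has the product form", {
  th <- theory_params(u0 = 0.8, x0 = 0.2, j_peak = 1)
  expect_equal(jux_group(0, th), 0.8 * 0.2)
  th1 <- theory_params(u0 = 0.8, x0 = 1, j_peak = 1)
  t <- seq(0, 3, 0.1)
  expect_equal(jux_group(t, th1), 0.8 * exp(-t / th1$tau_f))
  # shift relation between groups: the trace of an earlier item at time t
  # equals the later item's trace at t + t*, so the pairwise contrasts of
  # the three-item task are time-shifted copies of each other
  d <- delta_jux_three(t, th)
  d_shift <- delta_jux_three(t + th$t_star, th)
  expect_equal(d$delta_jux[d$pair == "12"],
               d_shift$delta_jux[d_shift$pair == "23"], tolerance = 1e-12)
})

test_that("two-item relative efficacy crosses zero once, or never", {
  th <- theory_params(u0 = 0.8, x0 = 0.2, tau_f = 4, tau_d = 0.3,
                      t_star = 1.25)
  # no depression (x0 = 1): later item always stronger, no crossing
  th1 <- theory_params(u0 = 0.8, x0 = 1, tau_f = 4, tau_d = 0.3,
                       t_star = 1.25)
  t <- seq(0, 10, 0.05)
  expect_true(all(delta_jux_two(t, th1) > 0))
  expect_true(is.na(tc_exact(th1)))
  expect_equal(delta_jux_two(1e9, th), 0)
  expect_gt(delta_jux_two(50, th), 0)   # approaches zero from above

  # bisection oracle on the stated example
  root <- stats::uniroot(function(t) delta_jux_two(t, th), c(1e-6, 1),
                         tol = 1e-12)$root
  expect_equal(root, 0.32, tolerance = 0.02)
  expect_equal(tc_exact(th), root, tolerance = 1e-9)
  # crossing sign: negative before, positive after
  expect_lt(delta_jux_two(root - 0.05, th), 0)
  expect_gt(delta_jux_two(root + 0.05, th), 0)
})

test_that("closed-form crossover equals the bisection root on random draws", {
  set.seed(21)
  n_checked <- 0
  for (i in 1:100) {
    th <- theory_params(
      u0 = runif(1, 0.3, 1), x0 = runif(1, 0.05, 0.9),
      tau_f = runif(1, 2, 8), tau_d = runif(1, 0.1, 0.4),
      t_star = runif(1, 0.25, 2.25)
    )
    tc <- tc_exact(th)
    lo <- delta_jux_two(1e-9, th)
    if (is.na(tc)) {
      expect_gte(lo, 0)
    } else {
      root <- stats::uniroot(function(t) delta_jux_two(t, th),
                             c(1e-9, 20), tol = 1e-12)$root
      expect_equal(tc, root, tolerance = 1e-9)
      n_checked <- n_checked + 1
    }
  }
  expect_gt(n_checked, 50)
})

test_that("crossover is monotone in the STP constants and the stride", {
  tf <- seq(2, 8, length.out = 5)
  td <- seq(0.1, 0.4, length.out = 5)
  ts <- seq(0.25, 2.25, length.out = 5)
  tc <- array(NA_real_, c(5, 5, 5))
  for (i in 1:5) for (j in 1:5) for (k in 1:5) {
    tc[i, j, k] <- tc_exact(list(x0 = 0.2, tau_f = tf[i], tau_d = td[j],
                                 t_star = ts[k]))
  }
  expect_true(all(is.finite(tc)))
  expect_true(all(apply(tc, c(2, 3), diff) >= 0))            # up in tau_f
  expect_true(all(apply(tc, c(1, 3), diff) >= 0))            # up in tau_d
  expect_true(all(apply(tc, c(1, 2), diff) <= 0))            # down in t*
})

test_that("simplified crossover approximates the exact one with a bias", {
  th <- theory_params(u0 = 0.8, x0 = 0.2, tau_f = 4, tau_d = 0.3,
                      t_star = 1.25, t_b = 0)
  expect_equal(tc_simplified(th), tc_exact(th), tolerance = 0.05)
  thb <- th
  thb$t_b <- 0.1
  expect_equal(tc_simplified(thb), tc_simplified(th) + 0.1)
  # the dropped factor vanishes as tau_d/tau_f -> 0
  th2 <- theory_params(u0 = 0.8, x0 = 0.2, tau_f = 400, tau_d = 0.01,
                       t_star = 1.25, t_b = 0)
  expect_equal(tc_simplified(th2), tc_exact(th2), tolerance = 1e-6)
})

test_that("three-item crossovers follow the shift relation", {
  th <- theory_params(u0 = 0.9, x0 = 0.1, tau_f = 2, tau_d = 0.4,
                      t_star = 0.4, t_b = 0.05)
  tc3 <- tc_three_items(th)
  expect_equal(tc3$pair, c("12", "23"))
  expect_equal(tc3$tc[2] - tc3$tc[1], th$t_star)
  expect_lt(tc3$tc[1], tc3$tc[2])
  expect_equal(tc3$tc[2], tc_simplified(th))

  # brute-force roots of the pairwise traces
  dj <- function(t, pair) {
    d <- delta_jux_three(t, th)
    d$delta_jux[d$pair == pair]
  }
  r12 <- stats::uniroot(function(t) dj(t, "12"), c(1e-9, 5),
                        tol = 1e-12)$root
  r23 <- stats::uniroot(function(t) dj(t, "23"), c(1e-9, 5),
                        tol = 1e-12)$root
  # biases excluded: raw roots differ by t* as well
  expect_equal(r23 - r12, th$t_star, tolerance = 1e-9)
  # the 2-3 contrast is the two-item contrast, so its root is the exact
  # two-item crossover; tc_three_items uses the facilitation-dominant
  # approximation on top of it
  expect_equal(r23, tc_exact(th), tolerance = 1e-9)
  expect_lt(abs((tc3$tc[2] - th$t_b) - r23) / r23, 0.3)

  # ordering holds across random parameter draws
  set.seed(31)
  for (i in 1:25) {
    thr <- theory_params(u0 = runif(1, 0.3, 1), x0 = runif(1, 0.05, 0.9),
                         tau_f = runif(1, 2, 8), tau_d = runif(1, 0.1, 0.4),
                         t_star = runif(1, 0.25, 2.25))
    v <- tc_three_items(thr)$tc
    if (!any(is.na(v))) expect_lt(v[1], v[2])
  }
})

test_that("theory grids evaluate vectorized over parameters", {
  g <- theory_grid(tau_f = c(2, 4, 8), tau_d = c(0.1, 0.3),
                   t_gap = c(0.5, 1))
  expect_equal(nrow(g), 12)
  expect_true(all(c("tc_exact", "tc_simplified") %in% names(g)))
  one <- theory_params(u0 = 0.8, x0 = 0.2, tau_f = 2, tau_d = 0.1,
                       t_star = 0.75)
  expect_equal(g$tc_exact[g$tau_f == 2 & g$tau_d == 0.1 & g$t_gap == 0.5],
               tc_exact(one))
})
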