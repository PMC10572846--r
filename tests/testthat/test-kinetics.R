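test_that("exp_conv matches closed forms and the quadrature oracle", {
  flat <- input_function(seq(0, 40, 1 / 60), rep(1, 2401), t2 = 20)
  # constant input: (1 - exp(-lam t)) / lam
  expect_equal(exp_conv(flat, 0.23, 0, 10), (1 - exp(-2.3)) / 0.23,
               tolerance = 1e-10)
  # lam = 0 degenerates to the running integral
  expect_equal(exp_conv(flat, 0, 0, c(5, 10)), c(5, 10), tolerance = 1e-10)
  # double-bolus curve vs adaptive quadrature
  ca <- test_input()
  for (tt in c(5, 15, 30)) {
    expect_equal(exp_conv(ca, 0.23, 0, tt), conv_quad_oracle(ca, 0.23, tt),
                 tolerance = 1e-6)
  }
  expect_error(exp_conv(ca, -0.1, 0, 5), "lam")
  expect_error(exp_conv(ca, 0.2, 0, 45), "t_eval")
})

test_that("baseline solution matches limits and the ODE oracle", {
  ca <- test_input()
  # no trapping: cm identically zero
  s <- solve_baseline(kinetic_params(0.2, 0.3, 0), ca, c(5, 10, 19))
  expect_equal(s$cm, rep(0, 3))
  # constant input, steady state of the free compartment: K1 C0 / (k2 + k3)
  flat <- input_function(seq(0, 400, 0.5), rep(100, 801), t2 = 200)
  s <- solve_baseline(kinetic_params(0.1, 0.15, 0.08), flat, 199)
  expect_equal(s$cf, 0.1 * 100 / 0.23, tolerance = 1e-6)
  # ODE oracle
  p <- kinetic_params(0.1, 0.15, 0.08)
  f <- stats::approxfun(ca$time, ca$ca)
  orc <- ode_oracle(p, f, 0, 18)
  s <- solve_baseline(p, ca, 18)
  expect_equal(s$cf, orc[1], tolerance = 1e-5)
  expect_equal(s$cm, orc[2], tolerance = 1e-5)
})

test_that("activation solution continues the baseline exactly", {
  ca <- test_input()
  p <- kinetic_params(0.1, 0.15, 0.08)
  b <- solve_baseline(p, ca, 20)
  te <- c(22, 30, 39)
  # identical parameters: piecewise result equals one continuous solution
  a <- solve_activation(p, ca, c(b$cf, b$cm), te)
  one <- solve_baseline(p, input_function(ca$time, ca$ca, t2 = 39.5), te)
  expect_equal(a$ct, one$ct, tolerance = 1e-9)
  # Ca = 0 from t2 on: cf decays homogeneously, cm grows only by the
  # trapped share of the decaying boundary free tracer
  ca0 <- input_function(ca$time, ifelse(ca$time >= 20, 0, ca$ca), t2 = 20)
  b0 <- solve_baseline(p, ca0, 20)
  a0 <- solve_activation(p, ca0, c(b0$cf, b0$cm), te)
  lam <- p$k2 + p$k3
  expect_equal(a0$cf, b0$cf * exp(-lam * (te - 20)), tolerance = 1e-9)
  expect_equal(a0$cm,
               b0$cm + p$k3 / lam * b0$cf * (1 - exp(-lam * (te - 20))),
               tolerance = 1e-9)
  # ODE oracle restarted at t2 with the baseline terminal state
  p2 <- kinetic_params(0.13, 0.15, 0.104)
  f <- stats::approxfun(ca$time, ca$ca)
  s2 <- ode_oracle(p, f, 0, 20)
  orc <- ode_oracle(p2, f, 20, 35, state0 = s2)
  a2 <- solve_activation(p2, ca, c(b$cf, b$cm), 35)
  expect_equal(a2$cf, orc[1], tolerance = 1e-5)
  expect_equal(a2$cm, orc[2], tolerance = 1e-5)
  expect_error(solve_activation(p2, ca, t_eval = 30), "baseline_state")
})

test_that("predict_tac frame averages match a brute-force fine grid", {
  ca <- test_input()
  sched <- test_schedule()
  # constant total activity: every frame equals the constant
  flat <- input_function(seq(0, 40, 1 / 60), rep(50, 2401), t2 = 20)
  pt <- predict_tac(kinetic_params(0, 0, 0, v0 = 1), NULL, flat, sched)
  expect_equal(pt$values, rep(50, 34))
  # one frame over a linear ramp from 0 to x averages to x / 2
  ramp <- input_function(c(0, 0.25, 40), c(0, 1000, 1000), t2 = 20)
  one <- frame_schedule(0, 0.25)
  pt <- predict_tac(kinetic_params(0, 0, 0, v0 = 1), NULL, ramp, one)
  expect_equal(pt$values, 500, tolerance = 1e-9)
  # full 34-frame schedule vs ~1 ms averaging oracle
  p <- kinetic_params(0.1, 0.15, 0.05, v0 = 0.05)
  pa <- kinetic_params(0.13, 0.15, 0.05, v0 = 0.05)
  pt <- predict_tac(p, pa, ca, sched)
  g <- seq(0, 20, length.out = 4001)
  b <- solve_baseline(p, ca, g)
  g2 <- seq(20, 40, length.out = 4001)
  a <- solve_activation(pa, ca, c(b$cf[4001], b$cm[4001]), g2)
  orc <- frame_avg_oracle(c(g, g2[-1]), c(b$ct, a$ct[-1]),
                          sched$start, sched$end)
  expect_equal(pt$values, orc, tolerance = 1e-3)
})

test_that("net uptake rate, delta Ki and CMRglucose arithmetic", {
  expect_equal(net_uptake_rate(kinetic_params(0.2, 0.3, 0)), 0)
  expect_equal(net_uptake_rate(kinetic_params(0.2, 0, 0.1)), 0.2)
  expect_equal(net_uptake_rate(kinetic_params(0.1, 0.15, 0.08)),
               0.1 * 0.08 / 0.23)
  expect_error(net_uptake_rate(-0.1, 0.1, 0.1), ">= 0")

  expect_equal(delta_ki(0.03, 0.03), 0)
  expect_equal(delta_ki(0.020, 0.032), 60)
  expect_equal(delta_ki(0.020, 0.032, denominator = "activation"), 37.5)
  expect_true(is.na(delta_ki(0, 0.03)))
  expect_true(is.na(delta_ki(0.03, 0, denominator = "activation")))

  expect_equal(cmr_glucose(0, 5.44, 0.65), 0)
  expect_equal(cmr_glucose(0.031, 1, 1), 0.031)
  expect_equal(cmr_glucose(0.0348, 5.44, 0.65), 0.0348 * 5.44 / 0.65)
  expect_error(cmr_glucose(0.03, 5.44, 0), "lc")
})

test_that("model invariants: conservation, monotone trapping, Ki ordering", {
  ca <- test_input()
  set.seed(4)
  for (i in 1:20) {
    p <- kinetic_params(runif(1, 0.02, 0.3), runif(1, 0.05, 0.5),
                        runif(1, 0.01, 0.2), v0 = runif(1, 0, 0.1))
    te <- round(sort(runif(8, 0.1, 20)), 6)
    s <- solve_baseline(p, ca, te)
    cav <- stats::approx(ca$time, ca$ca, xout = te)$y
    expect_equal(s$ct, s$cf + s$cm + p$v0 * cav, tolerance = 1e-12)
    expect_true(all(diff(s$cm) >= -1e-9))
  }
  # Ki monotone: increasing in K1 and k3, decreasing in k2
  ki <- net_uptake_rate(kinetic_params(0.1, 0.15, 0.08))
  expect_gt(net_uptake_rate(kinetic_params(0.12, 0.15, 0.08)), ki)
  expect_gt(net_uptake_rate(kinetic_params(0.1, 0.15, 0.1)), ki)
  expect_lt(net_uptake_rate(kinetic_params(0.1, 0.2, 0.08)), ki)
})

test_that("PVC rescaling of Ca, K1 and V0 leaves curves and delta Ki alone", {
  ca <- test_input()
  c0 <- 2.5
  ca2 <- input_function(ca$time, ca$ca * c0, t2 = 20, pvc = c0)
  p <- kinetic_params(0.1, 0.15, 0.08, v0 = 0.06)
  ps <- kinetic_params(0.1 / c0, 0.15, 0.08, v0 = 0.06 / c0)
  te <- c(3, 10, 19)
  s1 <- solve_baseline(p, ca, te)
  s2 <- solve_baseline(ps, ca2, te)
  expect_equal(s1$ct, s2$ct, tolerance = 1e-12)
  # Ki scales by 1/c, so the relative change is invariant
  expect_equal(net_uptake_rate(ps), net_uptake_rate(p) / c0)
  expect_equal(
    delta_ki(net_uptake_rate(p), 1.3 * net_uptake_rate(p)),
    delta_ki(net_uptake_rate(ps), 1.3 * net_uptake_rate(ps))
  )
})
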