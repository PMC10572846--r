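test_that("Gaussian frame smoothing behaves like the explicit kernel", {
  sched <- frame_schedule(0, 1)
  d <- array(0, c(15, 15, 15, 1))
  d[8, 8, 8, 1] <- 1000
  dyn <- dynamic_image(d, sched, c(2, 2, 2))
  # fwhm 0 is the identity
  expect_identical(smooth_frames(dyn, 0)$data, dyn$data)
  sm <- smooth_frames(dyn, 8)
  # delta spike spreads into a Gaussian with sigma = 8/2.3548/2 voxels
  sig <- 8 / (2 * sqrt(2 * log(2))) / 2
  off <- (-7):7
  k <- exp(-off^2 / (2 * sig^2)); k <- k / sum(k)
  orc <- 1000 * outer(outer(k, k), k)
  expect_equal(as.vector(sm$data[, , , 1]), as.vector(orc), tolerance = 1e-6)
  # total preserved away from edges
  expect_equal(sum(sm$data), 1000, tolerance = 1e-3)
  # uniform frame unchanged in the interior
  du <- dynamic_image(array(5, c(15, 15, 15, 1)), sched, c(2, 2, 2))
  smu <- smooth_frames(du, 8)
  expect_equal(smu$data[8, 8, 8, 1], 5, tolerance = 1e-9)
})

test_that("baseline initialization recovers noiseless parameters", {
  ca <- test_input()
  sched <- test_schedule()
  cfg <- fit_config()
  p <- kinetic_params(0.1, 0.15, 0.08)
  y <- simulate_tac(p, NULL, ca, sched, noise_scale = 0)
  est <- fit_baseline_initial(y, ca, cfg)
  expect_equal(est$k1, p$k1, tolerance = 0.01)
  expect_equal(est$k2, p$k2, tolerance = 0.01)
  expect_equal(est$k3, p$k3, tolerance = 0.01)
  expect_true(attr(est, "fit")$converged)
  # zero curve: K1 pinned at the lower bound, flagged degenerate
  y0 <- tac(sched, rep(0, 34))
  est0 <- fit_baseline_initial(y0, ca, cfg)
  expect_equal(est0$k1, 0)
  expect_true(attr(est0, "fit")$bound_hit[1])
})

test_that("noisy single-curve recovery has small median Ki bias", {
  ca <- test_input()
  sched <- test_schedule()
  cfg <- fit_config()
  p <- kinetic_params(0.1, 0.15, 0.08)
  set.seed(21)
  ki <- replicate(50, {
    y <- simulate_tac(p, NULL, ca, sched)
    net_uptake_rate(fit_baseline_initial(y, ca, cfg))
  })
  truth <- net_uptake_rate(p)
  expect_lt(abs(median(ki) - truth) / truth, 0.05)
})

test_that("raw refit respects its box and freezes k3 bit-for-bit", {
  ca <- test_input()
  sched <- test_schedule()
  cfg <- fit_config()
  p <- kinetic_params(0.1, 0.15, 0.08)
  y <- simulate_tac(p, NULL, ca, sched, noise_scale = 0)
  init <- fit_baseline_initial(y, ca, cfg)
  # raw data equal to the initialization data: returns the init values
  re <- refit_baseline_raw(y, init, ca, cfg)
  expect_equal(re$k1, init$k1, tolerance = 1e-4)
  expect_equal(re$k2, init$k2, tolerance = 1e-4)
  expect_identical(re$k3, init$k3)
  # raw curve generated with K1 five times the init: pinned at the 4x bound
  y5 <- simulate_tac(kinetic_params(0.5, 0.15, 0.08), NULL, ca, sched,
                     noise_scale = 0)
  re5 <- refit_baseline_raw(y5, init, ca, cfg)
  expect_equal(re5$k1, 4 * init$k1, tolerance = 1e-6)
  expect_true(attr(re5, "fit")$bound_hit[1])
  # frozen k3 under noise
  yn <- simulate_tac(p, NULL, ca, sched, seed = 5)
  ren <- refit_baseline_raw(yn, init, ca, cfg)
  expect_identical(ren$k3, init$k3)
})

test_that("early-phase V0 estimation recovers the blood volume fraction", {
  ca <- test_input()
  sched <- test_schedule()
  cfg <- fit_config()
  p <- kinetic_params(0.1, 0.15, 0.05, v0 = 0.05)
  y <- simulate_tac(p, NULL, ca, sched, noise_scale = 0)
  v0 <- estimate_v0(y, kinetic_params(p$k1, p$k2, p$k3), ca, cfg)
  expect_equal(as.numeric(v0), 0.05, tolerance = 0.002)
  # v0 = 0 voxel
  p0 <- kinetic_params(0.1, 0.15, 0.05, v0 = 0)
  y0 <- simulate_tac(p0, NULL, ca, sched, noise_scale = 0)
  expect_lt(abs(as.numeric(estimate_v0(y0, p0, ca, cfg))), 0.002)
  # pure blood voxel: CT = Ca, K1 = 0 -> V0 = 1
  yb <- simulate_tac(kinetic_params(0, 0, 0, v0 = 1), NULL, ca, sched,
                     noise_scale = 0)
  expect_equal(as.numeric(estimate_v0(yb, kinetic_params(0, 0, 0), ca, cfg)),
               1, tolerance = 1e-6)
})

test_that("activation fit ties k3 and recovers programmed changes", {
  ca <- test_input()
  sched <- test_schedule()
  cfg <- fit_config()
  p <- kinetic_params(0.1, 0.15, 0.05, v0 = 0.05)
  # unchanged parameters: delta Ki about zero
  y <- simulate_tac(p, p, ca, sched, noise_scale = 0)
  f <- fit_tac(y, y, ca, cfg)
  expect_lt(abs(f$delta_ki), 2)
  # K1 increased by 30%, others equal: delta Ki 30 within 1 point
  pa <- kinetic_params(0.13, 0.15, 0.05, v0 = 0.05)
  y30 <- simulate_tac(p, pa, ca, sched, noise_scale = 0)
  f30 <- fit_tac(y30, y30, ca, cfg)
  expect_equal(f30$delta_ki, 30, tolerance = 1 / 30)
  # tied k3 is bit-identical across sessions
  expect_identical(f30$act$k3, f30$base$k3)
  yn <- simulate_tac(p, pa, ca, sched, seed = 9)
  fn <- fit_tac(yn, yn, ca, cfg)
  expect_identical(fn$act$k3, fn$base$k3)
  # constraint respect: parameters inside their boxes
  b <- cfg$activation_bound_factors
  expect_gte(fn$act$k1, b[1] * fn$base$k1)
  expect_lte(fn$act$k1, b[2] * fn$base$k1)
  expect_gte(fn$act$k2, b[1] * fn$base$k2)
  expect_lte(fn$act$k2, b[2] * fn$base$k2)
})

test_that("voxelwise fit recovers a toy image and tolerates empty masks", {
  ca <- test_input()
  sched <- test_schedule()
  p <- kinetic_params(0.1, 0.15, 0.05, v0 = 0.05)
  pars <- list(
    list(b = p, a = kinetic_params(0.13, 0.15, 0.05, v0 = 0.05)),
    list(b = p, a = p),
    list(b = kinetic_params(0.08, 0.12, 0.06, v0 = 0.03),
         a = kinetic_params(0.096, 0.12, 0.06, v0 = 0.03))
  )
  d <- array(0, c(3, 1, 1, 34))
  for (i in 1:3) {
    d[i, 1, 1, ] <- predict_tac(pars[[i]]$b, pars[[i]]$a, ca, sched)$values
  }
  dyn <- dynamic_image(d, sched, c(2.34, 2.34, 2.78))
  # no smoothing for a 3-voxel strip: voxels are independent
  cfg <- fit_config(smoothing_fwhm_mm = 0)
  maps <- fit_voxelwise(dyn, ca, voi_mask(array(TRUE, c(3, 1, 1))), cfg)
  truth_dki <- vapply(pars, function(q)
    delta_ki(net_uptake_rate(q$b), net_uptake_rate(q$a)), numeric(1))
  expect_equal(as.vector(maps$delta_ki), truth_dki, tolerance = 0.02)
  expect_equal(as.vector(maps$ki_baseline),
               vapply(pars, function(q) net_uptake_rate(q$b), numeric(1)),
               tolerance = 0.01)
  expect_equal(as.vector(maps$v0), c(0.05, 0.05, 0.03), tolerance = 0.002)
  # empty mask: empty maps, no error
  empty <- fit_voxelwise(dyn, ca, voi_mask(array(FALSE, c(3, 1, 1))), cfg)
  expect_true(all(is.na(empty$delta_ki)))
})

test_that("voxelwise results do not depend on processing order", {
  ca <- test_input()
  sched <- test_schedule()
  p <- kinetic_params(0.1, 0.15, 0.05, v0 = 0.05)
  pa <- kinetic_params(0.12, 0.15, 0.05, v0 = 0.05)
  set.seed(3)
  d <- array(0, c(4, 1, 1, 34))
  for (i in 1:4) {
    d[i, 1, 1, ] <- simulate_tac(p, pa, ca, sched, seed = i)$values
  }
  cfg <- fit_config(smoothing_fwhm_mm = 0)
  dyn <- dynamic_image(d, sched, c(2, 2, 2))
  maps1 <- fit_voxelwise(dyn, ca, voi_mask(array(TRUE, c(4, 1, 1))), cfg)
  # reversed voxel order via array flip, flipped back
  dyn_r <- dynamic_image(d[4:1, , , , drop = FALSE], sched, c(2, 2, 2))
  maps2 <- fit_voxelwise(dyn_r, ca, voi_mask(array(TRUE, c(4, 1, 1))), cfg)
  expect_identical(as.vector(maps1$delta_ki), rev(as.vector(maps2$delta_ki)))
})
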