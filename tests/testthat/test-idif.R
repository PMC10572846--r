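test_that("early image is the duration-weighted mean of overlapping frames", {
  sched <- frame_schedule(c(0, 0.5), c(0.5, 1))
  d <- array(0, c(2, 2, 2, 2))
  d[, , , 1] <- 2; d[, , , 2] <- 4
  dyn <- dynamic_image(d, sched, c(2, 2, 2))
  # window = one frame exactly
  expect_equal(make_early_image(dyn, c(0, 0.5))$volume, array(2, c(2, 2, 2)))
  # two equal-duration frames average with equal weight
  expect_equal(make_early_image(dyn, c(0, 1))$volume, array(3, c(2, 2, 2)))
  expect_error(make_early_image(dyn, c(2, 3)), "overlap")
  # full acquisition schedule, (0, 1) min window: explicit weighted sum over
  # the four 15 s frames
  sched34 <- test_schedule()
  set.seed(1)
  vals <- runif(34, 10, 100)
  d2 <- array(rep(vals, each = 8), c(2, 2, 2, 34))
  dyn2 <- dynamic_image(d2, sched34, c(2, 2, 2))
  ov <- pmin(sched34$end, 1) - pmax(sched34$start, 0)
  w <- pmax(ov, 0); w <- w / sum(w)
  expect_equal(make_early_image(dyn2, c(0, 1))$volume[1, 1, 1], sum(w * vals))
})

test_that("vessel segmentation thresholds and keeps the largest component", {
  ph <- fx("phantom_small", generate_phantom(small_phantom_spec()))
  early <- make_early_image(ph$image, c(0, 1))
  seg <- segment_vessels(early, 0.5)
  expect_equal(seg$voxels, ph$truth$vessel$voxels)
  # very high fraction: a non-empty subset of the vessel
  seg99 <- segment_vessels(early, 0.999)
  expect_true(any(seg99$voxels))
  expect_true(all(ph$truth$vessel$voxels[seg99$voxels]))
  # uniform image: degenerate, warns
  uni <- structure(list(volume = array(1, c(4, 4, 4)), window = c(0, 1)),
                   class = "fpet_early")
  expect_warning(segment_vessels(uni, 0.5), "uniform")
  dark <- structure(list(volume = array(c(-1, rep(-2, 63)), c(4, 4, 4)),
                         window = c(0, 1)), class = "fpet_early")
  expect_error(segment_vessels(dark, 0.5), "empty vessel mask")
})

test_that("dilation matches a brute-force physical-distance scan", {
  d <- c(9, 9, 9)
  m <- array(FALSE, d); m[5, 5, 5] <- TRUE
  m <- voi_mask(m)
  # radius 0 is the identity
  expect_equal(dilate_mask(m, 0, c(2, 2, 2))$voxels, m$voxels)
  # isotropic 2 mm voxels, 6 mm ball: 123-voxel digital ball
  di <- dilate_mask(m, 6, c(2, 2, 2))
  expect_equal(sum(di$voxels), 123)
  expect_equal(di$voxels, dilate_oracle(m$voxels, 6, c(2, 2, 2)))
  # anisotropic acquisition voxels: +/- 2 voxels on every axis
  vs <- c(2.34, 2.34, 2.78)
  da <- dilate_mask(m, 6, vs)
  expect_equal(da$voxels, dilate_oracle(m$voxels, 6, vs))
  idx <- which(da$voxels, arr.ind = TRUE)
  expect_equal(range(idx[, 1]), c(3, 7))
  expect_equal(range(idx[, 3]), c(3, 7))
  # monotone and commutes with union
  m2 <- array(FALSE, d); m2[2, 2, 2] <- TRUE; m2 <- voi_mask(m2)
  expect_true(all(da$voxels[m$voxels]))
  u <- voi_mask(m$voxels | m2$voxels)
  expect_equal(
    dilate_mask(u, 5, vs)$voxels,
    dilate_mask(m, 5, vs)$voxels | dilate_mask(m2, 5, vs)$voxels
  )
})

test_that("IDIF extraction subtracts background, rescales and clips", {
  ph <- fx("phantom_small", generate_phantom(small_phantom_spec()))
  vessel <- ph$truth$vessel
  bkg <- ph$truth$bkg
  # background is air (zero): Ca equals the vessel mean
  idif <- extract_idif(ph$image, vessel, bkg, pvc = 1, t2 = 20)
  idif_nb <- extract_idif(ph$image, vessel, NULL, pvc = 1, t2 = 20)
  expect_equal(idif$ca, idif_nb$ca, tolerance = 1e-12)
  # vessel == background value pattern: perfect cancellation
  dflat <- dynamic_image(array(7, c(4, 4, 4, 34)), test_schedule(), c(2, 2, 2))
  mv <- array(FALSE, c(4, 4, 4)); mv[1:2, , ] <- TRUE
  mb <- array(FALSE, c(4, 4, 4)); mb[3:4, , ] <- TRUE
  z <- extract_idif(dflat, voi_mask(mv), voi_mask(mb, "background"), t2 = 20)
  expect_true(all(z$ca == 0))
  # linear in the image: doubling all frames doubles Ca
  dyn2 <- dynamic_image(ph$image$data * 2, ph$image$schedule,
                        ph$image$voxel_size_mm)
  idif2 <- extract_idif(dyn2, vessel, bkg, pvc = 1, t2 = 20)
  expect_equal(idif2$ca, 2 * idif$ca, tolerance = 1e-12)
  # pvc rescales
  idif_p <- extract_idif(ph$image, vessel, bkg, pvc = 2, t2 = 20)
  expect_equal(idif_p$ca, idif$ca / 2, tolerance = 1e-12)
  # noiseless phantom: vessel voxels carry the true Ca; the recovered curve
  # tracks the frame-averaged truth (exactly on the slow 2-min frames, to
  # within the midpoint re-gridding error of the peak scale on the rapidly
  # varying 15 s frames) and peaks at the right frame
  truth_frames <- predict_tac(kinetic_params(0, 0, 0, v0 = 1), NULL,
                              ph$truth$ca, ph$image$schedule)
  mids <- (ph$image$schedule$start + ph$image$schedule$end) / 2
  rec <- stats::approx(idif$time, idif$ca, xout = mids)$y
  durs <- ph$image$schedule$end - ph$image$schedule$start
  long <- durs > 1
  expect_equal(rec[long], truth_frames$values[long], tolerance = 1e-5)
  expect_lt(max(abs(rec - truth_frames$values)) / max(truth_frames$values),
            0.03)
  expect_equal(which.max(rec), which.max(truth_frames$values))
  expect_error(extract_idif(ph$image, voi_mask(array(FALSE, dim(vessel$voxels)))),
               "empty")
})
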