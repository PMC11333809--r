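test_that("Patlak on zero tissue gives zero slope and intercept", {
  sched <- default_frame_schedule()
  mm <- fixture("mm_identity", {
    model_idif_and_tissue(default_plasma_params(),
                          tissue_params(0.102, 0.13, 0.062, 0),
                          mixing_params(), sched)
  })
  zero <- tacurve(rep(0, 38), sched$mid_s)
  pf <- patlak_fit(zero, mm$cp_frames)
  expect_equal(pf$Ki, 0)
  expect_equal(pf$intercept, 0)
})

test_that("Patlak recovers the analytic macro-parameter on clean curves", {
  p <- default_plasma_params()
  sched <- default_frame_schedule()
  set.seed(12)
  for (i in 1:5) {
    tp <- tissue_params(runif(1, 0.06, 0.14), runif(1, 0.15, 0.25),
                        runif(1, 0.05, 0.10), 0)
    mm <- model_idif_and_tissue(p, tp, mixing_params(), sched, dt = 0.2)
    pf <- patlak_fit(mm$ct_frames, mm$cp_frames, t_star_s = 1200)
    expect_equal(pf$Ki, ki_analytic(tp), tolerance = 0.02)
    expect_gte(pf$r_squared, 0.999)
  }
  # k4 > 0 bends the plot and lowers r^2
  tp0 <- tissue_params(0.1, 0.15, 0.05, 0)
  tp4 <- tissue_params(0.1, 0.15, 0.05, 0.02)
  mm0 <- model_idif_and_tissue(p, tp0, mixing_params(), sched, dt = 0.2)
  mm4 <- model_idif_and_tissue(p, tp4, mixing_params(), sched, dt = 0.2)
  r0 <- patlak_fit(mm0$ct_frames, mm0$cp_frames)$r_squared
  r4 <- patlak_fit(mm4$ct_frames, mm4$cp_frames)$r_squared
  expect_lt(r4, r0)
})

test_that("Patlak rejects unusable inputs", {
  sched <- default_frame_schedule()
  tac <- tacurve(rep(1, 38), sched$mid_s)
  expect_error(patlak_fit(tac, tac, t_star_s = 4000), "fewer than 2")
  bad <- tacurve(c(rep(1, 30), rep(-1, 8)), sched$mid_s)
  expect_error(patlak_fit(tac, bad, t_star_s = 1200), "positive")
})

test_that("the Ki map matches regional truth on a clean phantom", {
  ph <- phantom_clean()
  ki <- ki_map(ph$volume, ph$truth$plasma_frames, t_star_s = 1200,
               brain_mask = ph$truth$brain_mask)
  rep <- regional_zscores(ki, ph$truth$region_labels)
  expect_equal(rep$mean_Ki, unname(ph$truth$ki_true), tolerance = 0.05)
  # all-zero data gives an all-zero map
  zero_dyn <- dynamic_volume(ph$volume$data * 0, ph$volume$voxel_mm,
                             ph$volume$schedule)
  ki0 <- ki_map(zero_dyn, ph$truth$plasma_frames, 1200, ph$truth$brain_mask)
  expect_true(all(ki0 == 0))
})

test_that("z-scores standardize the regional means and flag only low outliers", {
  lab <- region_labels(array(rep(1:36, each = 4), dim = c(12, 12, 1)))
  ki <- array(rep(0.030, 36 * 4), dim = c(12, 12, 1))
  ki[lab$data == 9] <- 0.020
  rep <- regional_zscores(ki, lab)
  expect_true(rep$hypometabolic[9])
  expect_lt(rep$z_score[9], -2)
  expect_equal(sum(rep$hypometabolic), 1)
  expect_equal(mean(rep$z_score), 0, tolerance = 1e-12)
  expect_equal(sd(rep$z_score), 1, tolerance = 1e-12)
  # translation invariance of z
  rep2 <- regional_zscores(ki + 0.01, lab)
  expect_equal(rep2$z_score, rep$z_score)
  # degenerate distribution
  expect_error(regional_zscores(array(0.03, dim = dim(ki)), lab),
               "degenerate")
})

test_that("mean absolute Ki difference is a symmetric mean over the mask", {
  a <- array(runif(27), dim = c(3, 3, 3))
  m <- mask3d(array(1L, dim = c(3, 3, 3)))
  expect_equal(abs_ki_diff(a, a, m), 0)
  expect_equal(abs_ki_diff(a, a + 0.001, m), 0.001)
  b <- array(runif(27), dim = c(3, 3, 3))
  expect_equal(abs_ki_diff(a, b, m), abs_ki_diff(b, a, m))
  expect_error(abs_ki_diff(a, b, mask3d(array(0L, c(3, 3, 3)))), "empty")
})
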