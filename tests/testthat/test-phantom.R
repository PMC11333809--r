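test_that("without PSF or noise the carotid TAC is the plasma curve", {
  ph <- phantom_ideal()
  tac <- extract_tac(ph$volume, ph$truth$carotid_mask)
  truth <- ph$truth$plasma_frames$values
  expect_lt(max(abs(tac$values - truth)) / max(truth), 1e-6)
})

test_that("the PSF dilutes the carotid peak and spills blood into tissue", {
  ph0 <- phantom_ideal()
  ph1 <- phantom_clean()
  idif0 <- extract_tac(ph0$volume, ph0$truth$carotid_mask)$values
  idif1 <- extract_tac(ph1$volume, ph1$truth$carotid_mask)$values
  expect_lt(max(idif1), max(idif0))
  # blood spills into the adjacent tissue at the bolus frames
  shell <- dynpet:::carotid_tissue_shell(ph0$truth$carotid_mask, 2, 5)
  early <- which.max(idif0) + (-1:1)
  t0 <- extract_tac(ph0$volume, shell)$values
  t1 <- extract_tac(ph1$volume, shell)$values
  expect_true(all(t1[early] > t0[early]))
})

test_that("phantom generation is deterministic under a fixed seed", {
  a <- generate_phantom(phantom_spec(grid_shape = c(32, 32, 32), seed = 5))
  b <- generate_phantom(phantom_spec(grid_shape = c(32, 32, 32), seed = 5))
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$truth$region_labels$data, b$truth$region_labels$data)
})

test_that("region parcellation covers the brain with the requested labels", {
  ph <- phantom_default()
  lab <- ph$truth$region_labels
  expect_equal(lab$n_regions, 36)
  expect_setequal(unique(lab$data[lab$data > 0]), 1:36)
  expect_true(all(lab$data[ph$truth$brain_mask$data == 1L] > 0))
  # analytic Ki invariant of the truth object
  for (r in c(1, 18, 36)) {
    p <- ph$truth$region_params[[r]]
    expect_equal(ph$truth$ki_true[r], 60 * p$K1 * p$k3 / (p$k2 + p$k3))
  }
})

test_that("the Gaussian PSF conserves mass and has the requested width", {
  v <- array(0, dim = c(33, 33, 33))
  v[17, 17, 17] <- 1000
  expect_identical(apply_psf(v, 0, 2), v)
  b <- apply_psf(v, 4.1, 2)
  expect_lt(abs(sum(b) - sum(v)) / sum(v), 1e-3)
  expect_lt(max(b), max(v))
  # measure the full width at half maximum along x through the center (mm)
  prof <- b[, 17, 17]
  half <- max(prof) / 2
  above <- range(which(prof >= half))
  # linear interpolation at the half-maximum crossings
  lo <- above[1] - 1 + (prof[above[1] - 1] - half) /
    (prof[above[1] - 1] - prof[above[1]])
  hi <- above[2] + (prof[above[2]] - half) / (prof[above[2]] - prof[above[2] + 1])
  fwhm_mm <- (hi - lo) * 2
  expect_equal(fwhm_mm, 4.1, tolerance = 0.15)
})

test_that("noise scales down with frame duration and is reproducible", {
  sched <- parse_frame_schedule("1,10;1,300")
  arr <- array(1000, dim = c(24, 24, 24, 2))
  vol <- dynamic_volume(arr, 2, sched)
  expect_identical(add_noise(vol, 0)$data, vol$data)
  n1 <- add_noise(vol, 15, seed = 3)
  n2 <- add_noise(vol, 15, seed = 3)
  expect_identical(n1$data, n2$data)
  sd_short <- sd(n1$data[, , , 1] - 1000)
  sd_long <- sd(n1$data[, , , 2] - 1000)
  expect_gt(sd_short, sd_long)
  expect_equal(sd_short / sd_long, sqrt(300 / 10), tolerance = 0.1)
})

test_that("hypometabolic injection reduces Ki exactly and composes", {
  rp <- default_region_tissue_params(10, seed = 2)
  ki0 <- vapply(rp, ki_analytic, numeric(1))
  rp1 <- inject_hypometabolic_region(rp, 7, 0.3)
  ki1 <- vapply(rp1, ki_analytic, numeric(1))
  expect_equal(ki1[7], 0.7 * ki0[7])
  expect_equal(ki1[-7], ki0[-7])
  rp2 <- inject_hypometabolic_region(rp1, 7, 0.3)
  expect_equal(ki_analytic(rp2[[7]]), 0.49 * ki0[7])
  expect_error(inject_hypometabolic_region(rp, 99, 0.3), "unknown region")
  expect_error(inject_hypometabolic_region(rp, 7, 1.2), "reduction_fraction")
})
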