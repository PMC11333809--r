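test_that("the early-frame reference is the voxelwise mean", {
  sched <- frame_schedule(3, 60)
  v <- array(2, dim = c(6, 6, 6))
  arr <- array(c(v, v, v), dim = c(6, 6, 6, 3))
  dyn <- dynamic_volume(arr, 2, sched)
  expect_equal(reference_from_early_frames(dyn, 3), v)
  arr2 <- array(c(v, 3 * v, v), dim = c(6, 6, 6, 3))
  dyn2 <- dynamic_volume(arr2, 2, sched)
  expect_equal(reference_from_early_frames(dyn2, 2), 2 * v)
  expect_error(reference_from_early_frames(dyn, 0), "positive")
  expect_error(reference_from_early_frames(dyn, 10), "exceeds")
})

test_that("motion correction leaves a motion-free phantom untouched", {
  ph <- phantom_default()
  ref <- reference_from_early_frames(ph$volume, 14)
  # a handful of frames across the acquisition is representative
  for (f in c(3, 6, 20, 38)) {
    tr <- dynpet:::register_rigid(ph$volume$data[, , , f], ref,
                                  ph$volume$voxel_mm)
    expect_lt(max(abs(tr$angles_deg)), 0.1)
    expect_lt(max(abs(tr$shift_mm)), 0.1)
  }
})

test_that("an injected translation is recovered and MSE never increases", {
  ph <- phantom_default()
  dyn <- ph$volume
  ref <- reference_from_early_frames(dyn, 14)
  shift_mm <- c(6, 0, 0)  # content moved +3 voxels in x
  moved <- apply_rigid_transform(dyn$data[, , , 5],
                                 rigid_transform(c(0, 0, 0), shift_mm),
                                 dyn$voxel_mm)
  tr <- dynpet:::register_rigid(moved, ref, dyn$voxel_mm)
  expect_equal(tr$shift_mm[1], -6, tolerance = 0.5 / 6)
  corrected <- apply_rigid_transform(moved, tr, dyn$voxel_mm)
  expect_lt(mean((corrected - ref)^2), mean((moved - ref)^2))
})

test_that("center crops use the documented index arithmetic", {
  v <- array(seq_len(64^3), dim = c(64, 64, 64))
  expect_identical(center_crop(v, c(64, 64, 64)), v)
  cr <- center_crop(v, c(32, 32, 32))
  expect_identical(cr, v[17:48, 17:48, 17:48])
  v5 <- array(1:5, dim = c(5, 1, 1))
  expect_equal(as.vector(center_crop(v5, c(2, 1, 1))), c(2, 3))
  expect_error(center_crop(v5, c(9, 1, 1)), "crop larger")
})

test_that("frame selection applies the first-local-maximum rule", {
  # craft uniform frames whose cropped sums are S = (5, 20, 80, 150, 160)
  S <- c(5, 20, 80, 150, 160)
  sched <- frame_schedule(length(S), 10)
  arr <- array(rep(S, each = 8^3), dim = c(8, 8, 8, length(S)))
  dyn <- dynamic_volume(arr, 2, sched)
  sel <- select_reference_frame(dyn, n_frames = 5, crop_shape = c(4, 4, 4))
  expect_equal(sel$frame_index, 3)
  expect_equal(sel$curves$D, c(S[1], diff(S)) * 4^3)  # 64 voxels per crop
  expect_equal(cumsum(sel$curves$D), sel$curves$S)
  # scaling invariance
  sel2 <- select_reference_frame(dynamic_volume(arr * 17, 2, sched),
                                 n_frames = 5, crop_shape = c(4, 4, 4))
  expect_equal(sel2$frame_index, sel$frame_index)
})

test_that("a monotone ramp has no local maximum and demands manual choice", {
  S <- c(10, 20, 30, 40, 50)
  sched <- frame_schedule(length(S), 10)
  arr <- array(rep(S, each = 6^3), dim = c(6, 6, 6, length(S)))
  dyn <- dynamic_volume(arr, 2, sched)
  expect_error(select_reference_frame(dyn, n_frames = 5), "manual")
})

test_that("on phantoms the selected frame brackets the bolus peak", {
  ph <- phantom_clean()
  sel <- select_reference_frame(ph$volume)
  peak <- which.max(ph$truth$plasma_frames$values)
  expect_lte(abs(sel$frame_index - peak), 1)
})
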