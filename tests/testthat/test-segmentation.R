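test_that("the Dice coefficient matches its defining formula", {
  m <- array(0, dim = c(10, 10, 10)); m[1:100] <- 1
  expect_equal(dice_coefficient(m, m), 1)
  expect_equal(dice_coefficient(m, m * 0), 1e-5 / (100 + 1e-5))
  # 2 true voxels, 1 overlapping prediction
  a <- array(0, dim = c(3, 3, 3)); a[c(1, 2)] <- 1
  b <- array(0, dim = c(3, 3, 3)); b[1] <- 1
  expect_equal(dice_coefficient(a, b, smooth = 0), 2 / 3)
  expect_error(dice_coefficient(a, array(0, c(2, 2, 2))), "shape")
})

test_that("Dice and Jaccard obey their algebraic relation on hard masks", {
  set.seed(6)
  for (i in 1:25) {
    a <- array(as.integer(runif(216) > 0.6), dim = c(6, 6, 6))
    b <- array(as.integer(runif(216) > 0.6), dim = c(6, 6, 6))
    d <- dice_coefficient(a, b, smooth = 0)
    j <- jaccard_index(a, b, smooth = 0)
    if (is.finite(d) && is.finite(j)) {
      expect_equal(j, d / (2 - d), tolerance = 1e-9)
    }
  }
})

test_that("the combined loss is 0.5 Dice loss + 0.5 BCE, by independent oracle", {
  set.seed(7)
  g <- array(as.integer(runif(8) > 0.5), dim = c(2, 2, 2))
  p <- array(runif(8), dim = c(2, 2, 2))
  # independently coded components
  oracle_dice <- function(g, p, s) (2 * sum(g * p) + s) / (sum(g) + sum(p) + s)
  pc <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  oracle_bce <- -sum(g * log(pc) + (1 - g) * log(1 - pc)) / 8
  expect_equal(combined_loss(g, p),
               0.5 * (1 - oracle_dice(g, p, 1e-5)) + 0.5 * oracle_bce)
  # perfect hard prediction is (numerically) zero loss
  expect_lt(combined_loss(g, g * 1.0), 1e-5)
  # p == 0.5 everywhere makes the BCE term exactly ln 2
  p5 <- array(0.5, dim = c(2, 2, 2))
  expect_equal(combined_loss(g, p5) - 0.5 * (1 - oracle_dice(g, p5, 1e-5)),
               0.5 * log(2))
})

test_that("threshold/islands keeps the k largest components above min size", {
  grid <- array(0, dim = c(30, 30, 30))
  grid[1:10, 1:10, 1:5] <- 100      # 500 voxels
  grid[20:29, 20:29, 1:4] <- 100    # 400 voxels
  grid[15, 15, 20:29] <- 100        # 10 voxels
  m <- threshold_islands_segment(grid, 50, min_component_voxels = 50, keep_k = 2)
  expect_equal(sum(m$data), 900)
  expect_true(all(m$data[15, 15, 20:29] == 0))
  expect_warning(m0 <- threshold_islands_segment(grid, 1e6), "empty mask")
  expect_equal(sum(m0$data), 0)
})

test_that("the classical segmenter recovers the carotids on a clean phantom", {
  ph <- phantom_clean()
  sel <- select_reference_frame(ph$volume)
  fr <- ph$volume$data[, , , sel$frame_index]
  m <- threshold_islands_segment(fr, 0.5 * max(fr))
  expect_gte(dice_coefficient(ph$truth$carotid_mask, m$data * 1.0), 0.90)
})

test_that("component cleanup removes spurious blobs and never adds voxels", {
  ph <- phantom_clean()
  truth <- ph$truth$carotid_mask
  noisy <- truth$data
  noisy[2:3, 2:3, 2] <- 1L  # 8-voxel spurious blob far from the carotids
  noisy_m <- mask3d(noisy)
  d_before <- dice_coefficient(truth, noisy_m$data * 1.0)
  cleaned <- keep_largest_components(noisy_m, k = 2)
  expect_gt(dice_coefficient(truth, cleaned$data * 1.0), d_before)
  expect_lte(sum(cleaned$data), sum(noisy))
  expect_identical(keep_largest_components(cleaned, k = 2)$data, cleaned$data)
  empty <- mask3d(array(0L, dim = dim(noisy)))
  expect_equal(sum(keep_largest_components(empty)$data), 0)
})

test_that("augmentation is identity at zero magnitudes and label-consistent", {
  set.seed(8)
  vol <- array(runif(24^3), dim = c(24, 24, 24))
  msk <- mask3d(array(as.integer(runif(24^3) > 0.97), dim = c(24, 24, 24)))
  cfg0 <- augment_config(max_rotation_deg = 0, max_shift_vox = 0,
                         zoom_scale = 0, horizontal_flip = FALSE,
                         target_shape = c(24, 24, 24))
  id <- augment_pair(vol, msk, cfg0, seed = 1)
  expect_identical(id$volume, vol)
  expect_identical(id$mask$data, msk$data)
  cfg <- augment_config(target_shape = c(24, 24, 24))
  a1 <- augment_pair(vol, msk, cfg, seed = 42)
  a2 <- augment_pair(vol, msk, cfg, seed = 42)
  expect_identical(a1$volume, a2$volume)
  expect_identical(a1$mask$data, a2$mask$data)
})

test_that("augmented masks stay binary with roughly preserved foreground", {
  # a centred ball with clearance for the maximum shift, so the property
  # reflects the transform itself (zoom changes volume by at most
  # ~1.05^3 - 1 = 16%) rather than border clipping or corner discretization
  n <- 28
  ctr <- (n + 1) / 2
  g <- expand.grid(x = 1:n, y = 1:n, z = 1:n)
  ball <- (g$x - ctr)^2 + (g$y - ctr)^2 + (g$z - ctr)^2 <= 8^2
  vol <- array(as.numeric(ball), dim = c(n, n, n))
  msk <- mask3d(array(as.integer(ball), dim = c(n, n, n)))
  cfg <- augment_config(target_shape = c(n, n, n))
  fg0 <- sum(msk$data)
  for (s in 1:40) {
    a <- augment_pair(vol, msk, cfg, seed = s)
    expect_true(all(a$mask$data %in% c(0L, 1L)))
    expect_lt(abs(sum(a$mask$data) - fg0) / fg0, 0.2)
  }
})

test_that("the default policy expands 48 subjects to 144 items", {
  items <- lapply(1:48, function(i) {
    v <- array(stats::runif(12^3), dim = c(12, 12, 12))
    list(volume = v, mask = mask3d(array(as.integer(v > 0.9), dim = dim(v))),
         subject_id = paste0("s", i))
  })
  cfg <- augment_config(target_shape = c(12, 12, 12), seed = 2)
  expanded <- expand_training_set(items, cfg)
  expect_equal(length(expanded), 144)
  # augmented copies inherit their subject's id
  ids <- vapply(expanded, function(x) x$subject_id, character(1))
  expect_equal(unname(table(ids)[paste0("s", 1:48)]), rep(3L, 48),
               ignore_attr = TRUE)
})

test_that("fold assignment is subject-grouped with each subject held out once", {
  ids <- paste0("s", 1:10)
  folds <- fold_assignment(ids, k = 5, seed = 3)
  expect_setequal(names(folds), ids)
  expect_true(all(folds %in% 1:5))
  expect_equal(unname(table(folds)), rep(2L, 5), ignore_attr = TRUE)
  expect_error(fold_assignment(paste0("s", 1:3), k = 5), "fewer subjects")
})

test_that("the U-Net contract holds: shape, sigmoid range, SE gating", {
  cfg <- unet_config(c(16, 16, 16), depth = 3, base_filters = 4,
                     se_reduction = 2, seed = 9)
  model <- build_unet(cfg)
  # filter doubling with cap
  expect_equal(dynpet:::unet_channels(unet_config(c(64, 64, 64), depth = 5,
                                                  base_filters = 64)),
               c(64, 128, 256, 512, 512))
  x <- array(rnorm(16^3), dim = c(16, 16, 16))
  fw <- dynpet:::unet_forward(model, x, train = TRUE)
  expect_equal(dim(fw$prob), c(16, 16, 16))
  expect_true(all(fw$prob > 0 & fw$prob < 1))
  for (s in 1:2) {
    g <- fw$cache[[paste0("se", s)]]$g
    expect_true(all(g > 0 & g < 1))
  }
  expect_error(unet_config(c(20, 20, 20), depth = 4), "divisible")
  pm <- predict_mask(model, x)
  expect_true(all(pm$data %in% c(0L, 1L)))
})

test_that("a reduced network can fit one subject's carotids", {
  ph <- phantom_default()
  sel <- select_reference_frame(ph$volume)
  fr <- ph$volume$data[, , , sel$frame_index]
  cr <- crop_around_mask(fr / max(fr), ph$truth$carotid_mask, c(32, 32, 32),
                         jitter_vox = 2, seed = 1)
  cfg <- unet_config(c(32, 32, 32), depth = 3, base_filters = 8,
                     se_reduction = 4, epochs = 100, learning_rate = 3e-3,
                     seed = 2)
  model <- train_segmenter(list(cr), cfg)
  pm <- predict_mask(model, cr$volume)
  expect_gte(dice_coefficient(cr$mask, pm$data * 1.0), 0.95)
})
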