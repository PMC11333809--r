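test_that("identity-mixing curves are recovered almost exactly", {
  sched <- default_frame_schedule()
  mm <- model_idif_and_tissue(default_plasma_params(),
                              tissue_params(0.102, 0.13, 0.062, 0),
                              mixing_params(), sched)
  fit <- fit_mcif(mm$idif, mm$tissue, sched, n_starts = 2, seed = 1)
  expect_lt(rel_rmse(fit$mcif$values, mm$cp_frames$values), 0.01)
  expect_true(all(fit$mcif$values >= 0))
})

test_that("partial-volume degraded input functions are model-corrected", {
  sched <- default_frame_schedule()
  mix <- mixing_params(rb = 0.7, st = 0.3, sb = 0.05, rt = 0.95)
  mm <- model_idif_and_tissue(default_plasma_params(),
                              tissue_params(0.102, 0.13, 0.062, 0),
                              mix, sched)
  fit <- fit_mcif(mm$idif, mm$tissue, sched, n_starts = 2, seed = 1)
  truth <- mm$cp_frames$values
  expect_lt(rel_rmse(fit$mcif$values, truth), 0.05)
  expect_lt(abs(max(fit$mcif$values) - max(truth)) / max(truth), 0.05)
  # the corrected peak exceeds the measured (diluted) peak
  expect_gt(max(fit$mcif$values), max(mm$idif$values))
  expect_equal(fit$mixing$rb, 0.7, tolerance = 0.05)
})

test_that("fit_mcif validates its inputs", {
  sched <- default_frame_schedule()
  short <- tacurve(1:10, sched$mid_s[1:10])
  expect_error(fit_mcif(short, short, sched), "frames")
})

test_that("MCIF-net layers have exact backward passes", {
  set.seed(1)
  cfg <- mcif_net_config(time_steps = 6, lstm_units = 3, bigru_units = 2,
                         dropout = 0, epochs = 1, seed = 2)
  m <- build_mcif_net(cfg)
  X <- array(rnorm(12), dim = c(2, 6, 1))
  Y <- matrix(rnorm(12), 2, 6)
  fw <- dynpet:::mcif_net_forward(m, X, train = FALSE)
  gr <- dynpet:::mcif_net_backward(m, fw, 2 * (fw$pred - Y) / length(Y))
  lossfn <- function(mm) {
    mean((dynpet:::mcif_net_forward(mm, X, train = FALSE)$pred - Y)^2)
  }
  set.seed(5)
  dirs <- lapply(m$params, function(p) {
    d <- rnorm(length(p)); if (!is.null(dim(p))) dim(d) <- dim(p); d
  })
  eps <- 1e-6
  ma <- m; mb <- m
  for (nm in names(m$params)) {
    ma$params[[nm]] <- m$params[[nm]] + eps * dirs[[nm]]
    mb$params[[nm]] <- m$params[[nm]] - eps * dirs[[nm]]
  }
  num <- (lossfn(ma) - lossfn(mb)) / (2 * eps)
  ana <- sum(mapply(function(gv, dv) sum(gv * dv), gr[names(m$params)], dirs))
  expect_equal(ana, num, tolerance = 1e-5)
})

test_that("MCIF-net predictions keep the sequence length and input scale", {
  cfg <- mcif_net_config(lstm_units = 4, bigru_units = 4, dropout = 0,
                         epochs = 2, batch_size = 4, seed = 3)
  pairs <- synthesize_mcif_pairs(4, seed = 4)
  m <- train_mcif_net(pairs$X, pairs$Y, cfg)
  pred <- predict_mcif_matrix(m, pairs$X)
  expect_equal(dim(pred), dim(pairs$X))
  idif <- tacurve(pairs$idif[1, ], pairs$schedule$mid_s)
  out <- predict_mcif(m, idif)
  expect_equal(length(out$values), 38)
  expect_equal(out$times_s, idif$times_s)
  expect_error(train_mcif_net(pairs$X[, 1:10], pairs$Y[, 1:10], cfg), "steps")
})

test_that("a small MCIF-net learns the correction on a handful of pairs", {
  pairs <- synthesize_mcif_pairs(8, seed = 2)
  cfg <- mcif_net_config(lstm_units = 16, bigru_units = 16, dropout = 0,
                         epochs = 150, batch_size = 2, learning_rate = 5e-3,
                         seed = 1)
  m <- train_mcif_net(pairs$X, pairs$Y, cfg)
  final <- utils::tail(m$history$train_mse, 1)
  baseline <- mean((pairs$X - pairs$Y)^2)
  expect_lt(final, baseline / 3)
})

test_that("synthesized training pairs respect their mixing construction", {
  pairs <- synthesize_mcif_pairs(12, seed = 9)
  expect_true(all(pairs$meta$rb >= 0.6 & pairs$meta$rb <= 0.9))
  expect_equal(pairs$meta$st, 1 - pairs$meta$rb)
  expect_true(all(abs(apply(pairs$X, 1, min)) < 1e-12))
  expect_true(all(abs(apply(pairs$X, 1, max) - 1) < 1e-12))
  # MCIF peak always exceeds the degraded IDIF peak
  expect_true(all(apply(pairs$mcif, 1, max) > apply(pairs$idif, 1, max)))
})
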