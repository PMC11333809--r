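test_that("the plasma input vanishes at the appearance delay and at infinity", {
  p <- default_plasma_params()
  expect_equal(feng_plasma(p$tau, p), 0)
  expect_equal(feng_plasma(0, p), 0)
  expect_lt(feng_plasma(1e7, p), 1e-10)
})

test_that("with a pure bolus term the plasma peak has its closed form", {
  p <- plasma_input_params(A1 = 3000, A2 = 0, A3 = 0,
                           lambda1 = 0.07, lambda2 = 0.002,
                           lambda3 = 0.0002, tau = 15)
  t_peak <- p$tau + 1 / p$lambda1
  expect_equal(feng_plasma(t_peak, p), p$A1 / (p$lambda1 * exp(1)))
  tt <- seq(0, 200, by = 0.01)
  expect_equal(tt[which.max(feng_plasma(tt, p))], t_peak, tolerance = 1e-3)
})

test_that("two-tissue solution obeys its degenerate limits", {
  p <- default_plasma_params()
  tg <- seq(60, 3600, by = 60)
  expect_equal(two_tissue_tac(p, tissue_params(0, 0.1, 0.05, 0), tg),
               rep(0, length(tg)))
  # k2=k3=k4=0: pure integral of the input
  ct <- two_tissue_tac(p, tissue_params(0.1, 0, 0, 0), tg, dt = 0.05)
  K1 <- 0.1 / 60
  int_cp <- vapply(tg, function(tm)
    stats::integrate(function(u) feng_plasma(u, p), 0, tm,
                     subdivisions = 2000, rel.tol = 1e-9)$value, numeric(1))
  expect_lt(max(abs(ct - K1 * int_cp) / max(K1 * int_cp)), 1e-3)
})

test_that("two-tissue solution matches a stiff ODE integrator to 0.1%", {
  skip_if_not_installed("deSolve")
  p <- default_plasma_params()
  tg <- seq(30, 3600, by = 30)
  set.seed(11)
  for (i in 1:20) {
    tp <- tissue_params(runif(1, 0.02, 0.2), runif(1, 0.02, 0.3),
                        runif(1, 0.01, 0.15), runif(1, 0, 0.05))
    ct <- two_tissue_tac(p, tp, tg, dt = 0.05)
    rhs <- function(t, y, parms) {
      cp <- feng_plasma(t, p)
      list(c(parms["K1"] * cp - (parms["k2"] + parms["k3"]) * y[1] +
               parms["k4"] * y[2],
             parms["k3"] * y[1] - parms["k4"] * y[2]))
    }
    sol <- deSolve::lsoda(c(0, 0), c(0, tg), rhs, parms = unlist(tp),
                          rtol = 1e-9, atol = 1e-9)
    ct_ode <- rowSums(sol[-1, 2:3, drop = FALSE])
    expect_lt(max(abs(ct - ct_ode)) / max(ct_ode), 1e-3)
  }
})

test_that("frame averaging is exact on constants and linear curves", {
  sched <- parse_frame_schedule("1,10;2,20")
  expect_equal(frame_average(function(t) rep(3.5, length(t)), sched)$values,
               c(3.5, 3.5, 3.5))
  lin <- frame_average(function(t) t, sched)
  expect_equal(lin$values[1], 5, tolerance = 1e-9)   # mean of t on [0,10]
  expect_equal(length(lin$values), n_frames(sched))
})

test_that("identity mixing returns the frame-averaged plasma curve exactly", {
  mm <- fixture("mm_identity", {
    model_idif_and_tissue(default_plasma_params(),
                          tissue_params(0.102, 0.13, 0.062, 0),
                          mixing_params(), default_frame_schedule())
  })
  expect_equal(mm$idif$values, mm$cp_frames$values)
  expect_equal(mm$tissue$values, mm$ct_frames$values)
})

test_that("mixing is the stated convex arithmetic and dilutes the peak", {
  p <- default_plasma_params()
  tp <- tissue_params(0.102, 0.13, 0.062, 0)
  sched <- default_frame_schedule()
  mm0 <- fixture("mm_identity", {
    model_idif_and_tissue(p, tp, mixing_params(), sched)
  })
  set.seed(4)
  for (i in 1:5) {
    rb <- runif(1, 0.4, 0.95); st <- runif(1, 0.05, 0.5)
    mm <- model_idif_and_tissue(p, tp, mixing_params(rb, st, 0.05, 0.95), sched)
    expect_equal(mm$idif$values,
                 rb * mm0$cp_frames$values + st * mm0$ct_frames$values)
    # partial volume: the measured peak is below the true plasma peak
    expect_lt(max(mm$idif$values), max(mm0$cp_frames$values))
  }
  # single-point arithmetic: rb=0.6, st=0.4 on Cp=100, Ct=10
  expect_equal(0.6 * 100 + 0.4 * 10, 64)
})

test_that("extract_tac averages voxels inside the mask", {
  sched <- frame_schedule(2, 60)
  arr <- array(7, dim = c(4, 4, 4, 2))
  vol <- dynamic_volume(arr, 2, sched)
  m <- array(0L, dim = c(4, 4, 4)); m[1:2] <- 1L
  expect_equal(extract_tac(vol, mask3d(m))$values, c(7, 7))
  arr[1, 1, 1, ] <- 10; arr[2, 1, 1, ] <- 20
  vol2 <- dynamic_volume(arr, 2, sched)
  expect_equal(extract_tac(vol2, mask3d(m))$values, c(15, 15))
  expect_error(extract_tac(vol, mask3d(array(0L, c(4, 4, 4)))), "empty")
})

test_that("min-max normalization round-trips and rejects constants", {
  tac <- tacurve(c(0, 5, 10), c(5, 15, 35))
  nz <- normalize_curve(tac)
  expect_equal(nz$values, c(0, 0.5, 1))
  expect_equal(denormalize_curve(nz)$values, tac$values, tolerance = 1e-9)
  expect_error(normalize_curve(tacurve(c(2, 2, 2), c(1, 2, 3))), "constant")
})

test_that("curve metrics follow their definitions", {
  truth <- c(1, 2, 3, 4)
  expect_equal(unlist(curve_metrics(truth, truth)),
               c(mse = 0, mae = 0, rmse = 0, mape = 0))
  m <- curve_metrics(truth + 1, truth)
  expect_equal(m$mae, 1); expect_equal(m$mse, 1); expect_equal(m$rmse, 1)
  set.seed(5)
  for (i in 1:10) {
    a <- rnorm(10); b <- rnorm(10)
    mm <- curve_metrics(a, b)
    expect_equal(mm$rmse, sqrt(mm$mse))
  }
  # zero-truth frames excluded from MAPE
  expect_equal(curve_metrics(c(1, 2), c(0, 2))$mape, 0)
  expect_error(curve_metrics(1:3, 1:4), "length")
})
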