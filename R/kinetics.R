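#' Kinetic parameter containers
#'
#' The plasma input is a Feng-type tri-exponential with an appearance delay:
#' seven parameters (`A1` in Bq/cc/s, `A2`, `A3` in Bq/cc, decay rates
#' `lambda1 > lambda2 > lambda3 > 0` in 1/s, delay `tau` in s). Tissue
#' kinetics follow the irreversible-friendly two-tissue compartment model
#' with rates `K1` (mL/cc/min), `k2`, `k3`, `k4` (1/min); rates are stored
#' internally in 1/s. Mixing parameters describe partial-volume and spillover
#' degradation: blood recovery `rb`, tissue-to-blood spillover `st`,
#' blood-to-tissue spillover `sb`, tissue recovery `rt`. Together these are
#' the 15 parameters of the model-corrected input function (MCIF) fit.
#'
#' @param A1,A2,A3 Amplitudes (Bq/cc/s, Bq/cc, Bq/cc).
#' @param lambda1,lambda2,lambda3 Decay rates in 1/s, strictly ordered
#'   `lambda1 > lambda2 > lambda3 > 0`.
#' @param tau Appearance delay in seconds (>= 0).
#' @return `plasma_input_params`: a named list of class `plasma_input_params`.
#' @export
plasma_input_params <- function(A1, A2 = 0, A3 = 0,
                                lambda1, lambda2, lambda3, tau = 0) {
  stopifnot(A1 > 0, A2 >= 0, A3 >= 0, tau >= 0)
  if (!(lambda1 > lambda2 && lambda2 > lambda3 && lambda3 > 0)) {
    stop("require lambda1 > lambda2 > lambda3 > 0", call. = FALSE)
  }
  structure(list(A1 = A1, A2 = A2, A3 = A3,
                 lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3,
                 tau = tau),
            class = "plasma_input_params")
}

#' @rdname plasma_input_params
#' @param K1,k2,k3,k4 Two-tissue rate constants, non-negative.
#' @param per Unit of the supplied rates: `"min"` (default, the conventional
#'   reporting unit) or `"s"`. Stored internally in 1/s.
#' @export
tissue_params <- function(K1, k2, k3, k4 = 0, per = c("min", "s")) {
  per <- match.arg(per)
  f <- if (per == "min") 1 / 60 else 1
  p <- c(K1 = K1, k2 = k2, k3 = k3, k4 = k4) * f
  if (any(p < 0)) stop("rate constants must be non-negative", call. = FALSE)
  structure(as.list(p), class = "tissue_params")
}

#' @rdname plasma_input_params
#' @param rb Blood recovery coefficient in (0, 1].
#' @param st Tissue-to-blood spillover fraction (>= 0).
#' @param sb Blood-to-tissue spillover fraction (>= 0).
#' @param rt Tissue recovery coefficient in (0, 1].
#' @export
mixing_params <- function(rb = 1, st = 0, sb = 0, rt = 1) {
  stopifnot(rb > 0, rb <= 1, st >= 0, sb >= 0, rt > 0, rt <= 1)
  structure(list(rb = rb, st = st, sb = sb, rt = rt), class = "mixing_params")
}

#' Net influx macro-parameter Ki = K1*k3/(k2+k3)
#'
#' Defined for irreversible tracers (`k4 = 0`); with `k4 > 0` it is the
#' asymptotic Patlak slope approximation.
#'
#' @param p A [tissue_params].
#' @param per Output unit, `"min"` (default) or `"s"`.
#' @return Ki in 1/min (or 1/s).
#' @export
ki_analytic <- function(p, per = c("min", "s")) {
  per <- match.arg(per)
  ki <- if (p$k2 + p$k3 <= 0) 0 else p$K1 * p$k3 / (p$k2 + p$k3)
  if (per == "min") ki * 60 else ki
}

#' Feng-type plasma input function
#'
#' \deqn{C_p(t) = [A_1 (t-\tau) - A_2 - A_3] e^{-\lambda_1 (t-\tau)} +
#'   A_2 e^{-\lambda_2 (t-\tau)} + A_3 e^{-\lambda_3 (t-\tau)}}
#' for \eqn{t > \tau}, and 0 before the appearance delay. Continuous at
#' \eqn{t = \tau} where it evaluates to 0.
#'
#' @param t Time(s) in seconds; vectorized.
#' @param p A [plasma_input_params].
#' @return Activity in Bq/cc at each `t`.
#' @export
feng_plasma <- function(t, p) {
  stopifnot(inherits(p, "plasma_input_params"))
  u <- t - p$tau
  out <- numeric(length(t))
  pos <- u > 0
  if (any(pos)) {
    up <- u[pos]
    out[pos] <- (p$A1 * up - p$A2 - p$A3) * exp(-p$lambda1 * up) +
      p$A2 * exp(-p$lambda2 * up) + p$A3 * exp(-p$lambda3 * up)
  }
  out
}

#' Default plasma-input parameters for phantom studies
#'
#' A bolus-plus-tail shape typical of an intravenous FDG injection: sharp
#' peak (~20 kBq/cc) within the first minute, slow tail of a few hundred
#' Bq/cc at 60 min. Decay rates follow the classic tri-exponential plasma
#' fits (fast bolus clearance ~4/min, intermediate ~0.12/min, slow
#' ~0.01/min).
#'
#' @return A [plasma_input_params].
#' @export
default_plasma_params <- function() {
  plasma_input_params(A1 = 4000, A2 = 800, A3 = 1100,
                      lambda1 = 4.1339 / 60, lambda2 = 0.1191 / 60,
                      lambda3 = 0.01043 / 60, tau = 20)
}

# O(n) causal convolution of y (on a uniform grid, spacing dt) with
# exp(-a t), trapezoidal within-step quadrature: a linear recurrence run
# through the C loop of stats::filter.
exp_conv <- function(y, a, dt) {
  n <- length(y)
  if (n == 0L) return(numeric(0))
  if (a * dt > 700) return(numeric(n))  # kernel underflows within one step
  kappa <- exp(-a * dt)
  u <- c(0, dt / 2 * (y[-1] + kappa * y[-n]))
  as.numeric(stats::filter(u, kappa, method = "recursive"))
}

# cumulative trapezoidal integral on a uniform grid
cum_trapz <- function(y, dt) {
  n <- length(y)
  c(0, cumsum((y[-1] + y[-n]) / 2)) * dt
}

#' Two-tissue compartment model tissue curve
#'
#' Solves the two-tissue compartment model for the total tissue activity
#' \deqn{C_t(t) = \frac{K_1}{\alpha_2-\alpha_1}\left[(k_3+k_4-\alpha_1)
#'   e^{-\alpha_1 t} + (\alpha_2-k_3-k_4) e^{-\alpha_2 t}\right] \ast C_p(t)}
#' with \eqn{\alpha_{1,2} = [(k_2+k_3+k_4) \mp
#' \sqrt{(k_2+k_3+k_4)^2 - 4 k_2 k_4}]/2}, evaluated by exponential
#' convolution on a fine uniform sub-grid and linearly interpolated onto
#' `t_grid`. Degenerate cases (`k2=k3=k4=0`, repeated roots) are handled by
#' their analytic limits.
#'
#' @param p_plasma A [plasma_input_params].
#' @param p_tissue A [tissue_params].
#' @param t_grid Increasing times (s) at which to return the tissue curve.
#' @param dt Fine-grid spacing in seconds (default 0.1).
#' @return Numeric vector of tissue activity (Bq/cc) at `t_grid`.
#' @export
two_tissue_tac <- function(p_plasma, p_tissue, t_grid, dt = 0.1) {
  stopifnot(inherits(p_tissue, "tissue_params"), all(diff(t_grid) > 0))
  t_max <- max(t_grid)
  t_fine <- seq(0, t_max + dt, by = dt)
  cp <- feng_plasma(t_fine, p_plasma)
  ct <- two_tissue_from_cp(cp, p_tissue, dt)
  stats::approx(t_fine, ct, xout = t_grid, rule = 2)$y
}

# tissue curve from a sampled plasma curve on a uniform grid
two_tissue_from_cp <- function(cp, p_tissue, dt) {
  K1 <- p_tissue$K1; k2 <- p_tissue$k2; k3 <- p_tissue$k3; k4 <- p_tissue$k4
  if (K1 == 0) return(numeric(length(cp)))
  s <- k2 + k3 + k4
  if (s < 1e-12) {
    # free + trapped pool with no egress: Ct = K1 * integral of Cp
    return(K1 * cum_trapz(cp, dt))
  }
  disc <- s^2 - 4 * k2 * k4
  disc <- max(disc, 0)
  a1 <- (s - sqrt(disc)) / 2
  a2 <- (s + sqrt(disc)) / 2
  if (a2 - a1 < 1e-10) {
    # repeated root: kernel K1*[1 + (k3+k4-a) t] e^{-a t}
    e1 <- exp_conv(cp, a1, dt)
    te <- exp_conv(e1, a1, dt)  # (e^{-at} * e^{-at})(t) = t e^{-at}
    return(K1 * (e1 + (k3 + k4 - a1) * te))
  }
  e1 <- if (a1 < 1e-12) cum_trapz(cp, dt) else exp_conv(cp, a1, dt)
  e2 <- exp_conv(cp, a2, dt)
  (K1 / (a2 - a1)) * ((k3 + k4 - a1) * e1 + (a2 - k3 - k4) * e2)
}

#' Frame-average a continuous curve over an acquisition schedule
#'
#' Returns the mean of `curve_fn` over each frame interval by composite
#' trapezoidal quadrature with at least `n_points` samples per frame.
#'
#' @param curve_fn Function of time (s), vectorized.
#' @param schedule A [frame_schedule].
#' @param n_points Quadrature points per frame (default 128).
#' @param label Optional label for the returned curve.
#' @return A [tacurve] of per-frame means at frame mid-times.
#' @export
frame_average <- function(curve_fn, schedule, n_points = 128, label = NULL) {
  stopifnot(inherits(schedule, "frame_schedule"), n_points >= 2)
  vals <- vapply(seq_len(n_frames(schedule)), function(i) {
    tt <- seq(schedule$start_s[i], schedule$end_s[i], length.out = n_points)
    y <- curve_fn(tt)
    sum((y[-1] + y[-n_points]) / 2) / (n_points - 1)
  }, numeric(1))
  tacurve(vals, schedule$mid_s, label = label)
}

# precompiled frame averager for repeated evaluations on the same fine grid
# (used inside optimization loops): boundary interpolation indices/weights
# into the cumulative trapezoid are computed once
make_frame_averager <- function(n_fine, dt, schedule) {
  pos <- function(t) {
    j <- pmin(pmax(t / dt, 0), n_fine - 1)
    i0 <- pmin(floor(j), n_fine - 2)
    list(i = i0 + 1L, w = j - i0)
  }
  ps <- pos(schedule$start_s)
  pe <- pos(schedule$end_s)
  dur <- schedule$durations_s
  function(values) {
    ct <- cum_trapz(values, dt)
    cs <- ct[ps$i] * (1 - ps$w) + ct[ps$i + 1L] * ps$w
    ce <- ct[pe$i] * (1 - pe$w) + ct[pe$i + 1L] * pe$w
    (ce - cs) / dur
  }
}

# frame-average a curve already sampled on a uniform fine grid starting at 0.
# Frame boundaries need not coincide with grid points; the cumulative
# trapezoid is interpolated at the boundaries.
frame_average_grid <- function(values, dt, schedule) {
  ct <- cum_trapz(values, dt)
  t_fine <- (seq_along(values) - 1) * dt
  cs <- stats::approx(t_fine, ct, xout = schedule$start_s, rule = 2)$y
  ce <- stats::approx(t_fine, ct, xout = schedule$end_s, rule = 2)$y
  (ce - cs) / schedule$durations_s
}

#' Model IDIF and tissue curves under partial-volume/spillover mixing
#'
#' Generates the frame-averaged plasma and tissue curves for given kinetic
#' parameters and mixes them into the measured pair:
#' `idif = rb*Cp + st*Ct` and `tissue = sb*Cp + rt*Ct` (frame-averaged).
#' With identity mixing (`rb = 1, st = sb = 0, rt = 1`) the IDIF equals the
#' frame-averaged plasma curve exactly.
#'
#' @param p_plasma A [plasma_input_params].
#' @param p_tissue A [tissue_params].
#' @param mix A [mixing_params].
#' @param schedule A [frame_schedule].
#' @param dt Fine-grid spacing (s) for the kinetic solution.
#' @return List with [tacurve]s `idif`, `tissue`, `cp_frames`, `ct_frames`.
#' @export
model_idif_and_tissue <- function(p_plasma, p_tissue, mix, schedule, dt = 0.1) {
  stopifnot(inherits(mix, "mixing_params"))
  t_fine <- seq(0, total_duration(schedule) + dt, by = dt)
  cp <- feng_plasma(t_fine, p_plasma)
  ct <- two_tissue_from_cp(cp, p_tissue, dt)
  cp_f <- frame_average_grid(cp, dt, schedule)
  ct_f <- frame_average_grid(ct, dt, schedule)
  mid <- schedule$mid_s
  list(idif = tacurve(mix$rb * cp_f + mix$st * ct_f, mid, label = "IDIF"),
       tissue = tacurve(mix$sb * cp_f + mix$rt * ct_f, mid, label = "tissue"),
       cp_frames = tacurve(cp_f, mid, label = "plasma"),
       ct_frames = tacurve(ct_f, mid, label = "tissue-true"))
}

#' Min-max normalization of a curve to [0, 1]
#'
#' @param tac A [tacurve] (non-constant).
#' @return A [tacurve] with values in `[0, 1]` and an attached `scale`
#'   attribute `(min, max)` for [denormalize_curve()].
#' @export
normalize_curve <- function(tac) {
  stopifnot(inherits(tac, "tacurve"))
  lo <- min(tac$values); hi <- max(tac$values)
  if (hi - lo <= 0) stop("cannot normalize a constant curve", call. = FALSE)
  out <- tacurve((tac$values - lo) / (hi - lo), tac$times_s, label = tac$label)
  attr(out, "scale") <- c(min = lo, max = hi)
  out
}

#' @rdname normalize_curve
#' @param scale Length-2 numeric `(min, max)`; defaults to the `scale`
#'   attribute attached by [normalize_curve()].
#' @export
denormalize_curve <- function(tac, scale = attr(tac, "scale")) {
  stopifnot(inherits(tac, "tacurve"), length(scale) == 2)
  tacurve(tac$values * (scale[2] - scale[1]) + scale[1], tac$times_s,
          label = tac$label)
}

#' Agreement metrics between two curves
#'
#' @param pred,truth Numeric vectors or [tacurve]s of equal length.
#' @return Named list: `mse`, `mae`, `rmse`, `mape` (percent; frames where
#'   `truth == 0` are excluded from MAPE).
#' @export
curve_metrics <- function(pred, truth) {
  if (inherits(pred, "tacurve")) pred <- pred$values
  if (inherits(truth, "tacurve")) truth <- truth$values
  if (length(pred) != length(truth)) {
    stop("curve lengths differ", call. = FALSE)
  }
  err <- pred - truth
  nz <- truth != 0
  list(mse = mean(err^2),
       mae = mean(abs(err)),
       rmse = sqrt(mean(err^2)),
       mape = if (any(nz)) 100 * mean(abs(err[nz] / truth[nz])) else NA_real_)
}
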