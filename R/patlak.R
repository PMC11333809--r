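#' Patlak graphical analysis of an irreversible tracer
#'
#' For frames with mid-time at or after `t_star_s`, regresses
#' \deqn{y(t) = C_t(t)/C_p(t) \quad \mathrm{on} \quad
#'   x(t) = \int_0^t C_p(\tau)\,d\tau \, / \, C_p(t)}
#' by ordinary least squares; the slope is the net influx rate Ki and the
#' intercept the effective distribution volume V. Because the sampled input
#' values are frame averages, the running integral is computed as the exact
#' frame-sum `sum(value * duration)` up to each frame mid (a trapezoidal
#' rule on mid-times undersamples the bolus peak, biasing Ki by up to a few
#' percent). For an irreversible two-tissue system (`k4 = 0`) the plot is
#' asymptotically linear with slope `K1*k3/(k2+k3)`.
#'
#' @param tissue Tissue [tacurve].
#' @param input_fn Plasma input [tacurve] on the same frame grid.
#' @param t_star_s Linear-phase onset in seconds (default 1200, i.e. the
#'   15–20 min post-injection equilibration).
#' @return A `patlak_result`: `Ki` (1/min), `intercept`, `r_squared`
#'   (clipped at 0), `t_star_s`, `n_points_used`.
#' @export
patlak_fit <- function(tissue, input_fn, t_star_s = 1200) {
  stopifnot(inherits(tissue, "tacurve"), inherits(input_fn, "tacurve"))
  if (length(tissue$values) != length(input_fn$values)) {
    stop("curves must share a schedule", call. = FALSE)
  }
  tt <- input_fn$times_s
  cp <- input_fn$values
  ct <- tissue$values
  int_cp <- patlak_running_integral(cp, tt)
  use <- tt >= t_star_s
  if (sum(use) < 2) stop("fewer than 2 frames at or after t*", call. = FALSE)
  if (any(cp[use] <= 0)) {
    stop("input function must be positive over the fitted frames", call. = FALSE)
  }
  x <- int_cp[use] / cp[use]
  y <- ct[use] / cp[use]
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  ssr <- sum((y - (intercept + slope * x))^2)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) max(0, 1 - ssr / sst) else 0
  structure(list(Ki = slope * 60, intercept = intercept, r_squared = r2,
                 t_star_s = t_star_s, n_points_used = sum(use)),
            class = "patlak_result")
}

# integral of the input up to each frame mid-time, treating the sampled
# values as frame averages over [start, end): exact for frame-averaged data
patlak_running_integral <- function(cp, tt) {
  n <- length(cp)
  # durations and starts recovered from mid-times of contiguous frames
  dur <- numeric(n)
  dur[1] <- 2 * tt[1]
  for (i in seq_len(n - 1)) dur[i + 1] <- 2 * (tt[i + 1] - tt[i]) - dur[i]
  if (any(dur <= 0)) {  # irregular grid: fall back to trapezoids
    seg <- c(0.5 * cp[1] * tt[1], (cp[-1] + cp[-n]) / 2 * diff(tt))
    return(cumsum(seg))
  }
  full <- cumsum(cp * dur)
  c(0, full[-n]) + cp * dur / 2
}

#' @export
print.patlak_result <- function(x, ...) {
  cat(sprintf("patlak_result: Ki %.5f /min, V %.3f, r^2 %.4f (%d frames, t* %.0f s)\n",
              x$Ki, x$intercept, x$r_squared, x$n_points_used, x$t_star_s))
  invisible(x)
}

#' Voxelwise Patlak Ki map
#'
#' Runs the Patlak regression at every voxel of `brain_mask` against a
#' shared input function (fully vectorized, since the regressor x depends
#' only on the input). Voxels outside the mask are 0; negative slopes are
#' clipped to 0 on the map, flagged in the attached `clipped` attribute and
#' counted in `n_clipped` (they are excluded from regional means
#' downstream).
#'
#' @param dyn A [dynamic_volume].
#' @param input_fn The plasma input [tacurve] (MCIF) on the same schedule.
#' @param t_star_s Linear-phase onset (s), default 1200.
#' @param brain_mask A [mask3d] of voxels to fit.
#' @return 3D array of Ki (1/min) with attributes `clipped` (logical array)
#'   and `n_clipped`.
#' @export
ki_map <- function(dyn, input_fn, t_star_s = 1200, brain_mask) {
  stopifnot(inherits(dyn, "dynamic_volume"), inherits(brain_mask, "mask3d"))
  check_spatial_alignment(dim(brain_mask$data), dyn, "brain mask")
  tt <- dyn$schedule$mid_s
  if (length(input_fn$values) != length(tt)) {
    stop("input function and volume disagree on frame count", call. = FALSE)
  }
  cp <- input_fn$values
  use <- tt >= t_star_s & cp > 0
  if (sum(use) < 2) stop("fewer than 2 usable frames at or after t*", call. = FALSE)
  x <- patlak_running_integral(cp, tt)[use] / cp[use]
  d <- dim(dyn$data)
  idx <- which(brain_mask$data != 0L)
  flat <- matrix(dyn$data, nrow = prod(d[1:3]), ncol = d[4])
  Y <- sweep(flat[idx, use, drop = FALSE], 2, cp[use], "/")
  xc <- x - mean(x)
  slope <- as.numeric(Y %*% xc - rowSums(Y) * mean(xc)) / sum(xc^2)
  ki <- slope * 60
  neg <- ki < 0
  out <- array(0, dim = d[1:3])
  out[idx] <- pmax(ki, 0)
  clipped <- array(FALSE, dim = d[1:3])
  clipped[idx[neg]] <- TRUE
  attr(out, "clipped") <- clipped
  attr(out, "n_clipped") <- sum(neg)
  out
}

#' Regional Ki means, z-scores and hypometabolism flags
#'
#' Averages the Ki map over each super-region (excluding voxels whose
#' negative slope was clipped by [ki_map()]), then standardizes each
#' regional mean against the mean and SD of all regional means (sample SD).
#' Regions with z below the cutoff (default -2 SD) are flagged
#' hypometabolic.
#'
#' @param ki_grid 3D Ki array from [ki_map()].
#' @param labels A [region_labels] aligned with the map.
#' @param z_cutoff Flagging threshold (default -2).
#' @return data.frame: `region_id`, `n_voxels`, `mean_Ki`, `z_score`,
#'   `hypometabolic`.
#' @export
regional_zscores <- function(ki_grid, labels, z_cutoff = -2) {
  stopifnot(inherits(labels, "region_labels"),
            all(dim(ki_grid) == dim(labels$data)))
  clipped <- attr(ki_grid, "clipped")
  ok <- labels$data > 0L
  if (!is.null(clipped)) ok <- ok & !clipped
  ids <- sort(unique(labels$data[labels$data > 0L]))
  if (length(ids) < 2) stop("need at least 2 regions", call. = FALSE)
  means <- vapply(ids, function(r) {
    v <- ki_grid[ok & labels$data == r]
    if (length(v) == 0) NA_real_ else mean(v)
  }, numeric(1))
  if (any(is.na(means))) stop("some regions have no usable voxels", call. = FALSE)
  mu <- mean(means)
  sigma <- stats::sd(means)
  if (sigma == 0) stop("degenerate region distribution (zero SD)", call. = FALSE)
  z <- (means - mu) / sigma
  data.frame(region_id = ids,
             n_voxels = vapply(ids, function(r) sum(ok & labels$data == r),
                               numeric(1)),
             mean_Ki = means, z_score = z,
             hypometabolic = z < z_cutoff)
}

#' Mean absolute Ki difference between two maps
#'
#' @param ki_grid_a,ki_grid_b 3D Ki arrays on the same grid.
#' @param brain_mask A [mask3d] of voxels to compare (non-empty).
#' @return Mean of `|a - b|` over the mask (1/min).
#' @export
abs_ki_diff <- function(ki_grid_a, ki_grid_b, brain_mask) {
  stopifnot(all(dim(ki_grid_a) == dim(ki_grid_b)),
            inherits(brain_mask, "mask3d"),
            all(dim(brain_mask$data) == dim(ki_grid_a)))
  idx <- which(brain_mask$data != 0L)
  if (length(idx) == 0) stop("empty mask", call. = FALSE)
  mean(abs(ki_grid_a[idx] - ki_grid_b[idx]))
}
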