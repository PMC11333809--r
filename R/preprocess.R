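#' Early-frame reference volume for motion correction
#'
#' Voxelwise mean of the first `n_frames` frames (default 14, the early
#' period with minimal subject motion and good signal-to-noise during bolus
#' transit), used as the registration reference.
#'
#' @param dyn A [dynamic_volume].
#' @param n_frames Number of leading frames to average (default 14).
#' @return 3D numeric array.
#' @export
reference_from_early_frames <- function(dyn, n_frames = 14) {
  stopifnot(inherits(dyn, "dynamic_volume"))
  nf <- dim(dyn$data)[4]
  if (n_frames <= 0) stop("n_frames must be positive", call. = FALSE)
  if (n_frames > nf) stop("n_frames exceeds the number of frames", call. = FALSE)
  out <- dyn$data[, , , 1]
  if (n_frames > 1) for (f in 2:n_frames) out <- out + dyn$data[, , , f]
  out / n_frames
}

#' Rigid transforms (3 rotations + 3 translations)
#'
#' A `rigid_transform` stores rotation angles in degrees and translations in
#' mm describing the motion applied to the image content; the identity is
#' all zeros. [apply_rigid_transform()] resamples a volume under the
#' transform with trilinear interpolation (out-of-grid voxels become 0).
#'
#' @param angles_deg Rotations about x, y, z in degrees.
#' @param shift_mm Translations in mm.
#' @return A `rigid_transform`.
#' @export
rigid_transform <- function(angles_deg = c(0, 0, 0), shift_mm = c(0, 0, 0)) {
  stopifnot(length(angles_deg) == 3, length(shift_mm) == 3)
  structure(list(angles_deg = as.numeric(angles_deg),
                 shift_mm = as.numeric(shift_mm)),
            class = "rigid_transform")
}

rotation_matrix <- function(angles_deg) {
  a <- angles_deg * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3)
  Rz %*% Ry %*% Rx
}

#' @rdname rigid_transform
#' @param volume_3d 3D array to resample.
#' @param transform A `rigid_transform`.
#' @param voxel_mm Voxel size(s) in mm.
#' @export
apply_rigid_transform <- function(volume_3d, transform, voxel_mm = c(1, 1, 1)) {
  stopifnot(length(dim(volume_3d)) == 3L, inherits(transform, "rigid_transform"))
  if (length(voxel_mm) == 1L) voxel_mm <- rep(voxel_mm, 3L)
  d <- dim(volume_3d)
  ctr <- (d - 1) / 2
  R <- rotation_matrix(transform$angles_deg)
  Rinv <- t(R)
  t_vox <- transform$shift_mm / voxel_mm
  # content transform p -> R(p-c)+c+t  =>  sample source at Rinv(v-c-t)+c
  offset <- as.numeric(Rinv %*% (-(ctr + t_vox))) + ctr
  A <- cbind(Rinv, offset)
  out <- cpp_affine_resample3d(as.double(volume_3d), d, A, d, FALSE)
  array(out, dim = d)
}

frame_mse <- function(a, b) mean((a - b)^2)

# integer-shift MSE over a small translation grid: a cheap global search
# that puts the local optimizer inside the capture range of small
# structures (the carotids are only ~2 voxels across)
coarse_shift_search <- function(mov, ref, max_shift = 4L, step = 2L) {
  d <- dim(mov)
  best <- c(0, 0, 0); best_mse <- frame_mse(mov, ref)
  offs <- seq(-max_shift, max_shift, by = step)
  for (dx in offs) for (dy in offs) for (dz in offs) {
    if (!dx && !dy && !dz) next
    sx <- intersect(seq_len(d[1]), seq_len(d[1]) - dx)
    sy <- intersect(seq_len(d[2]), seq_len(d[2]) - dy)
    sz <- intersect(seq_len(d[3]), seq_len(d[3]) - dz)
    m <- frame_mse(mov[sx + dx, sy + dy, sz + dz], ref[sx, sy, sz])
    if (m < best_mse) { best_mse <- m; best <- c(dx, dy, dz) }
  }
  best
}

register_rigid <- function(moving, reference, voxel_mm, maxit = 100,
                           min_improvement = 0.1) {
  d <- dim(moving)
  # coarse grid for the similarity metric (multi-resolution speed-up)
  sub <- lapply(d, function(n) seq(1, n, by = if (n >= 48) 2L else 1L))
  fac <- vapply(seq_len(3), function(i) if (d[i] >= 48) 2 else 1, numeric(1))
  vox_c <- voxel_mm * fac
  # pre-smooth both images: the metric then sees band-limited content, so
  # the low-pass effect of trilinear resampling cannot fake a lower MSE at
  # spurious sub-voxel offsets (threshold 10%: measured spurious gains from
  # bolus-frame content mismatch are ~2%, genuine voxel-scale motion >50%)
  mov_c <- apply_psf(moving[sub[[1]], sub[[2]], sub[[3]]], 2 * min(vox_c), vox_c)
  ref_c <- apply_psf(reference[sub[[1]], sub[[2]], sub[[3]]], 2 * min(vox_c), vox_c)
  obj <- function(p) {
    tr <- rigid_transform(p[1:3], p[4:6])
    frame_mse(apply_rigid_transform(mov_c, tr, vox_c), ref_c)
  }
  shift0 <- -coarse_shift_search(mov_c, ref_c) * vox_c  # content correction
  p0 <- c(0, 0, 0, shift0)
  fit <- tryCatch(
    stats::optim(p0, obj, method = "Nelder-Mead",
                 control = list(maxit = maxit, reltol = 1e-10)),
    error = function(e) NULL)
  if (is.null(fit)) {
    warning("rigid registration failed; keeping identity transform")
    return(rigid_transform())
  }
  # polish with a second restart from the optimum (Nelder-Mead stalls)
  fit2 <- tryCatch(
    stats::optim(fit$par, obj, method = "Nelder-Mead",
                 control = list(maxit = maxit, reltol = 1e-10)),
    error = function(e) NULL)
  if (!is.null(fit2) && fit2$value < fit$value) fit <- fit2
  tr <- rigid_transform(fit$par[1:3], fit$par[4:6])
  # acceptance is decided on a smoothed full-resolution metric: on noisy
  # frames, plain MSE rewards any transform simply because trilinear
  # resampling averages the noise away, so relative gains are measured on
  # band-limited images and must exceed min_improvement; on top of that a
  # transform must never make the plain MSE worse
  fwhm <- 2 * min(voxel_mm)
  mov_s <- apply_psf(moving, fwhm, voxel_mm)
  ref_s <- apply_psf(reference, fwhm, voxel_mm)
  gain_s <- 1 - frame_mse(apply_rigid_transform(mov_s, tr, voxel_mm), ref_s) /
    frame_mse(mov_s, ref_s)
  plain_worse <- frame_mse(apply_rigid_transform(moving, tr, voxel_mm), reference) >
    frame_mse(moving, reference)
  if (gain_s < min_improvement || plain_worse) {
    return(rigid_transform())
  }
  tr
}

#' Rigid motion correction of a dynamic volume
#'
#' Registers every frame to the reference by minimizing the mean squared
#' intensity difference over the six rigid parameters (Nelder-Mead on a
#' coarse grid, trilinear resampling, out-of-grid = 0). A frame's corrected
#' MSE never exceeds its uncorrected MSE: if optimization fails to improve
#' on the identity, the identity transform is kept.
#'
#' @param dyn A [dynamic_volume].
#' @param reference 3D array on the same grid (see
#'   [reference_from_early_frames()]).
#' @param maxit Optimizer iteration cap per frame.
#' @return List: `volume` (corrected [dynamic_volume]) and `transforms`
#'   (per-frame [rigid_transform]s).
#' @export
motion_correct <- function(dyn, reference, maxit = 100) {
  stopifnot(inherits(dyn, "dynamic_volume"),
            all(dim(reference) == dim(dyn$data)[1:3]))
  nf <- dim(dyn$data)[4]
  out <- dyn$data
  transforms <- vector("list", nf)
  for (f in seq_len(nf)) {
    tr <- register_rigid(dyn$data[, , , f], reference, dyn$voxel_mm,
                         maxit = maxit)
    transforms[[f]] <- tr
    if (any(tr$angles_deg != 0) || any(tr$shift_mm != 0)) {
      out[, , , f] <- apply_rigid_transform(dyn$data[, , , f], tr, dyn$voxel_mm)
    }
  }
  list(volume = dynamic_volume(out, dyn$voxel_mm, dyn$schedule, dyn$affine),
       transforms = transforms)
}

#' Central crop of a 3D volume
#'
#' Extracts the central `crop_shape` sub-grid; when the remainder per axis is
#' odd, the extra voxel is kept on the high-index side.
#'
#' @param volume_3d 3D array.
#' @param crop_shape Integer length-3 target shape (each <= grid shape).
#' @return Cropped 3D array.
#' @export
center_crop <- function(volume_3d, crop_shape) {
  d <- dim(volume_3d)
  stopifnot(length(d) == 3L, length(crop_shape) == 3L)
  if (any(crop_shape > d)) stop("crop larger than grid", call. = FALSE)
  idx <- lapply(seq_len(3), function(i) {
    start <- floor((d[i] - crop_shape[i]) / 2)  # 0-based
    seq.int(start + 1L, start + crop_shape[i])
  })
  volume_3d[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

#' Select the carotid-clear reference frame from the bolus transit
#'
#' Computes the summed intensity `S` of the center-cropped region over the
#' first `n_frames` frames and the difference series `D` (`D[1] = S[1]`,
#' `D[i] = S[i] - S[i-1]`). The selected frame is the one immediately before
#' the first interior local maximum of `D` (smallest `i` with
#' `D[i] > D[i-1]` and `D[i] >= D[i+1]`): at that moment most tracer is
#' still in transit through the carotids, which are therefore clearest for
#' segmentation. The choice is invariant to positive intensity rescaling.
#'
#' @param dyn A [dynamic_volume].
#' @param n_frames How many leading frames to examine (default 10, >= 3).
#' @param crop_shape Central crop used for the intensity sums; default half
#'   the grid per axis.
#' @return List: `frame_index` (1-based index of the selected frame) and
#'   `curves` (list with `S` and `D`).
#' @export
select_reference_frame <- function(dyn, n_frames = 10, crop_shape = NULL) {
  stopifnot(inherits(dyn, "dynamic_volume"), n_frames >= 3)
  d <- dim(dyn$data)
  n_frames <- min(n_frames, d[4])
  if (is.null(crop_shape)) crop_shape <- pmax(1L, floor(d[1:3] / 2))
  S <- vapply(seq_len(n_frames), function(f)
    sum(center_crop(dyn$data[, , , f], crop_shape)), numeric(1))
  D <- c(S[1], diff(S))
  sel <- NA_integer_
  for (i in seq(2, n_frames - 1)) {
    if (D[i] > D[i - 1] && D[i] >= D[i + 1]) { sel <- i - 1L; break }
  }
  if (is.na(sel)) {
    stop(paste("no interior local maximum in the intensity-difference curve;",
               "select the reference frame manually"), call. = FALSE)
  }
  list(frame_index = sel, curves = list(S = S, D = D))
}
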