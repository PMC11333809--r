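#' Augmentation policy for segmentation training
#'
#' Each training pair is transformed by an identical random affine —
#' rotations up to `max_rotation_deg` degrees, shifts up to `max_shift_vox`
#' voxels, zooms within `1 +/- zoom_scale` — optionally mirrored across the
#' midline and warped by a smooth random elastic field, then zero-padded or
#' center-cropped to `target_shape`. The volume is interpolated trilinearly,
#' the mask by nearest neighbour and re-binarized. The default policy
#' expands each subject to `expansion_factor` training items (the original
#' plus `expansion_factor - 1` augmented copies).
#'
#' @param max_rotation_deg Maximum rotation per axis in degrees (default 4).
#' @param max_shift_vox Maximum shift per axis in voxels (default 5).
#' @param zoom_scale Zoom half-range (default 0.05).
#' @param elastic Apply a smooth random displacement field (default FALSE).
#' @param elastic_amp_vox Elastic displacement amplitude in voxels.
#' @param horizontal_flip Allow mirroring across the first axis (default
#'   TRUE).
#' @param target_shape Output grid (default `c(128,128,128)`; set smaller
#'   for phantom work).
#' @param expansion_factor Total items produced per input pair (default 3).
#' @param seed Integer seed.
#' @return An `augment_config`.
#' @export
augment_config <- function(max_rotation_deg = 4, max_shift_vox = 5,
                           zoom_scale = 0.05, elastic = FALSE,
                           elastic_amp_vox = 2, horizontal_flip = TRUE,
                           target_shape = c(128, 128, 128),
                           expansion_factor = 3, seed = 1) {
  stopifnot(max_rotation_deg >= 0, max_shift_vox >= 0, zoom_scale >= 0,
            elastic_amp_vox >= 0, expansion_factor >= 1)
  structure(list(max_rotation_deg = max_rotation_deg,
                 max_shift_vox = max_shift_vox, zoom_scale = zoom_scale,
                 elastic = isTRUE(elastic), elastic_amp_vox = elastic_amp_vox,
                 horizontal_flip = isTRUE(horizontal_flip),
                 target_shape = as.integer(target_shape),
                 expansion_factor = as.integer(expansion_factor),
                 seed = as.integer(seed)),
            class = "augment_config")
}

#' Zero-pad or center-crop a 3D array to a target shape
#'
#' For odd pad/crop remainders the extra voxel goes to the high-index side,
#' matching [center_crop()].
#'
#' @param volume_3d 3D array.
#' @param target_shape Integer length-3 shape.
#' @return 3D array of shape `target_shape`.
#' @export
pad_or_crop <- function(volume_3d, target_shape) {
  d <- dim(volume_3d)
  crop <- pmin(d, target_shape)
  out <- center_crop(volume_3d, crop)
  if (all(crop == target_shape)) return(out)
  res <- array(0, dim = target_shape)
  start <- floor((target_shape - crop) / 2)  # 0-based
  res[start[1] + seq_len(crop[1]), start[2] + seq_len(crop[2]),
      start[3] + seq_len(crop[3])] <- out
  res
}

# vectorized trilinear gather at fractional 0-based coordinates
trilinear_gather <- function(vol, px, py, pz) {
  d <- dim(vol)
  x0 <- floor(px); y0 <- floor(py); z0 <- floor(pz)
  fx <- px - x0; fy <- py - y0; fz <- pz - z0
  acc <- numeric(length(px))
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    ix <- x0 + dx; iy <- y0 + dy; iz <- z0 + dz
    ok <- ix >= 0 & ix < d[1] & iy >= 0 & iy < d[2] & iz >= 0 & iz < d[3]
    w <- (if (dx) fx else 1 - fx) * (if (dy) fy else 1 - fy) *
      (if (dz) fz else 1 - fz)
    idx <- ix[ok] + d[1] * (iy[ok] + d[2] * iz[ok]) + 1
    acc[ok] <- acc[ok] + w[ok] * vol[idx]
  }
  acc
}

# smooth random displacement field: coarse Gaussian noise blurred and
# scaled to the requested amplitude
elastic_field <- function(d, amp_vox) {
  lapply(1:3, function(i) {
    f <- array(stats::rnorm(prod(d)), dim = d)
    f <- apply_psf(f, fwhm_mm = 8, voxel_mm = 1)
    f * (amp_vox / max(abs(f), 1e-12))
  })
}

#' Apply one random augmentation to a volume/mask pair
#'
#' The same sampled transform is applied to both; the result is a pure
#' function of `(volume, mask, cfg, seed)` so a repeated call reproduces it
#' exactly.
#'
#' @param volume_3d 3D array.
#' @param mask A [mask3d] aligned with `volume_3d`.
#' @param cfg An [augment_config].
#' @param seed Integer seed for this draw.
#' @return List `volume`, `mask` (a [mask3d]), both of `cfg$target_shape`.
#' @export
augment_pair <- function(volume_3d, mask, cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "augment_config"), inherits(mask, "mask3d"),
            all(dim(volume_3d) == dim(mask$data)))
  set.seed(seed)
  angles <- stats::runif(3, -cfg$max_rotation_deg, cfg$max_rotation_deg)
  shift <- stats::runif(3, -cfg$max_shift_vox, cfg$max_shift_vox)
  zoom <- stats::runif(1, 1 - cfg$zoom_scale, 1 + cfg$zoom_scale)
  flip <- cfg$horizontal_flip && stats::runif(1) < 0.5

  d <- dim(volume_3d)
  identity_affine <- all(angles == 0) && all(shift == 0) && zoom == 1 && !flip
  if (identity_affine && !cfg$elastic) {
    return(list(volume = pad_or_crop(volume_3d, cfg$target_shape),
                mask = mask3d(pad_or_crop(mask$data, cfg$target_shape))))
  }

  ctr <- (d - 1) / 2
  R <- rotation_matrix(angles)
  S <- diag(3) / zoom
  if (flip) S[1, 1] <- -S[1, 1]
  M <- S %*% t(R)  # sample source at M (v - c - shift) + c
  offset <- as.numeric(M %*% (-(ctr + shift))) + ctr
  A <- cbind(M, offset)

  if (cfg$elastic && cfg$elastic_amp_vox > 0) {
    gg <- expand.grid(x = 0:(d[1] - 1), y = 0:(d[2] - 1), z = 0:(d[3] - 1))
    fld <- elastic_field(d, cfg$elastic_amp_vox)
    px <- A[1, 1] * gg$x + A[1, 2] * gg$y + A[1, 3] * gg$z + A[1, 4] + as.vector(fld[[1]])
    py <- A[2, 1] * gg$x + A[2, 2] * gg$y + A[2, 3] * gg$z + A[2, 4] + as.vector(fld[[2]])
    pz <- A[3, 1] * gg$x + A[3, 2] * gg$y + A[3, 3] * gg$z + A[3, 4] + as.vector(fld[[3]])
    vol <- array(trilinear_gather(volume_3d, px, py, pz), dim = d)
    mk <- array(trilinear_gather(mask$data * 1.0, px, py, pz), dim = d)
  } else {
    vol <- array(cpp_affine_resample3d(as.double(volume_3d), d, A, d, FALSE), dim = d)
    mk <- array(cpp_affine_resample3d(as.double(mask$data), d, A, d, TRUE), dim = d)
  }
  mk <- array(as.integer(mk >= 0.5), dim = d)
  list(volume = pad_or_crop(vol, cfg$target_shape),
       mask = mask3d(array(as.integer(pad_or_crop(mk, cfg$target_shape) >= 0.5),
                           dim = cfg$target_shape)))
}

#' Expand a training set under the augmentation policy
#'
#' Each input item (a list with `volume`, `mask` and `subject_id`) yields
#' `cfg$expansion_factor` output items: the original, padded/cropped to the
#' target shape, plus augmented copies. Augmented copies keep their
#' subject's id, so subject-grouped fold assignments are inherited.
#'
#' @param items List of items (`volume`, `mask`, `subject_id`).
#' @param cfg An [augment_config].
#' @return Expanded list of items.
#' @export
expand_training_set <- function(items, cfg) {
  stopifnot(inherits(cfg, "augment_config"))
  out <- list()
  for (i in seq_along(items)) {
    it <- items[[i]]
    out[[length(out) + 1L]] <- list(
      volume = pad_or_crop(it$volume, cfg$target_shape),
      mask = mask3d(pad_or_crop(it$mask$data, cfg$target_shape)),
      subject_id = it$subject_id)
    if (cfg$expansion_factor > 1L) {
      for (j in seq_len(cfg$expansion_factor - 1L)) {
        aug <- augment_pair(it$volume, it$mask, cfg,
                            seed = cfg$seed + 7919L * i + j)
        out[[length(out) + 1L]] <- list(volume = aug$volume, mask = aug$mask,
                                        subject_id = it$subject_id)
      }
    }
  }
  out
}
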