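#' Specification of a synthetic dynamic FDG-PET phantom
#'
#' The phantom emulates a 38-frame, 60-minute dynamic FDG acquisition: two
#' high-uptake carotid tubes carrying the plasma curve, embedded in a
#' soft-tissue head ellipsoid whose upper portion holds a brain ellipsoid
#' partitioned into `region_count` contiguous super-regions (a seeded,
#' mirror-symmetric Voronoi parcellation, 18 per side by default). Each
#' frame is blurred by an isotropic Gaussian point-spread function and
#' degraded by frame-duration-dependent Gaussian noise.
#'
#' @param grid_shape Integer length-3 grid dimensions (default `c(64,64,64)`).
#' @param voxel_mm Isotropic voxel size in mm (default 2).
#' @param carotid_radius_mm Carotid tube radius (default 2.5 mm).
#' @param carotid_offset_mm Lateral distance of each tube from the midline
#'   (default 14 mm, i.e. tubes 28 mm apart).
#' @param carotid_z_frac Fractional z-extent of the tubes (default lower
#'   third, `c(0.10, 0.30)`, entirely below the brain ellipsoid — the
#'   cervical/petrous course the IDIF is read from — so the vessels'
#'   surroundings are a single soft-tissue compartment).
#' @param region_count Number of brain super-regions (default 36).
#' @param psf_fwhm_mm Scanner point-spread FWHM (default 4.1 mm).
#' @param noise_scale Noise magnitude; per-voxel-per-frame SD is
#'   `noise_scale * sqrt(max(value,0)/duration_s)` (default 15).
#' @param seed Integer seed controlling parcellation, kinetics and noise.
#' @param schedule A [frame_schedule] (default the 38-frame protocol).
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(grid_shape = c(64, 64, 64), voxel_mm = 2,
                         carotid_radius_mm = 2.5, carotid_offset_mm = 14,
                         carotid_z_frac = c(0.10, 0.30),
                         region_count = 36, psf_fwhm_mm = 4.1,
                         noise_scale = 15, seed = 1,
                         schedule = default_frame_schedule()) {
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 16),
            voxel_mm > 0, carotid_radius_mm > 0, psf_fwhm_mm >= 0,
            noise_scale >= 0, region_count >= 2)
  structure(list(grid_shape = as.integer(grid_shape), voxel_mm = voxel_mm,
                 carotid_radius_mm = carotid_radius_mm,
                 carotid_offset_mm = carotid_offset_mm,
                 carotid_z_frac = carotid_z_frac,
                 region_count = as.integer(region_count),
                 psf_fwhm_mm = psf_fwhm_mm, noise_scale = noise_scale,
                 seed = as.integer(seed), schedule = schedule),
            class = "phantom_spec")
}

# geometry masks in voxel space (1-based continuous coordinates)
phantom_geometry <- function(spec) {
  d <- spec$grid_shape
  cx <- (d[1] + 1) / 2; cy <- (d[2] + 1) / 2; cz <- (d[3] + 1) / 2
  xg <- seq_len(d[1]); yg <- seq_len(d[2]); zg <- seq_len(d[3])
  X <- array(rep(xg, times = d[2] * d[3]), dim = d)
  Y <- array(rep(rep(yg, each = d[1]), times = d[3]), dim = d)
  Z <- array(rep(zg, each = d[1] * d[2]), dim = d)

  head_mask <- ((X - cx) / (0.42 * d[1]))^2 + ((Y - cy) / (0.42 * d[2]))^2 +
    ((Z - cz) / (0.48 * d[3]))^2 <= 1
  bz <- 0.62 * d[3]
  brain_mask <- ((X - cx) / (0.36 * d[1]))^2 + ((Y - cy) / (0.36 * d[2]))^2 +
    ((Z - bz) / (0.30 * d[3]))^2 <= 1
  brain_mask <- brain_mask & head_mask

  r_vox <- spec$carotid_radius_mm / spec$voxel_mm
  off_vox <- spec$carotid_offset_mm / spec$voxel_mm
  zlo <- spec$carotid_z_frac[1] * d[3]; zhi <- spec$carotid_z_frac[2] * d[3]
  in_z <- Z >= zlo & Z <= zhi
  left <- ((X - (cx - off_vox))^2 + (Y - cy)^2) <= r_vox^2 & in_z
  right <- ((X - (cx + off_vox))^2 + (Y - cy)^2) <= r_vox^2 & in_z
  if (any(left & right)) stop("carotid tubes overlap; reduce radius or increase offset")
  carotid <- (left | right) & head_mask
  if (!any(carotid)) stop("carotid tubes fall outside the head; check spec")
  brain_mask <- brain_mask & !carotid

  list(head = head_mask, brain = brain_mask, carotid = carotid,
       coords = list(X = X, Y = Y, Z = Z),
       center = c(cx, cy, cz))
}

# mirror-symmetric seeded Voronoi parcellation of the brain ellipsoid
phantom_parcellation <- function(spec, geom) {
  d <- spec$grid_shape
  R <- spec$region_count
  half <- R %/% 2
  idx <- which(geom$brain)
  X <- geom$coords$X[idx]; Y <- geom$coords$Y[idx]; Z <- geom$coords$Z[idx]
  cx <- geom$center[1]
  set.seed(spec$seed)
  # centroids drawn on the left half, mirrored to the right
  left_vox <- which(X < cx)
  if (length(left_vox) < half) stop("brain too small for requested region count")
  pick <- sample(left_vox, half)
  cent <- cbind(X[pick], Y[pick], Z[pick])
  cent <- rbind(cent, cbind(2 * cx - cent[, 1], cent[, 2], cent[, 3]))
  if (nrow(cent) > R) cent <- cent[seq_len(R), , drop = FALSE]
  # nearest-centroid assignment
  d2 <- outer(X, cent[, 1], "-")^2 + outer(Y, cent[, 2], "-")^2 +
    outer(Z, cent[, 3], "-")^2
  lab_vals <- max.col(-d2)
  lab <- array(0L, dim = d)
  lab[idx] <- lab_vals
  region_labels(lab)
}

#' Default per-region tissue kinetics for a phantom
#'
#' Gray-matter-like FDG kinetics (K1 ~ 0.10 mL/cc/min, k2 ~ 0.13/min,
#' k3 ~ 0.06/min, k4 = 0 for irreversible trapping) with modest
#' inter-regional heterogeneity: independent log-normal multipliers
#' (sdlog 0.03 per rate constant, about 4-5% CV on the resulting Ki).
#'
#' @param n_regions Number of regions.
#' @param seed Integer seed.
#' @param base A [tissue_params] around which regions vary.
#' @param sdlog Log-scale SD of the per-region rate multipliers.
#' @return List of `n_regions` [tissue_params] (per-second units internally).
#' @export
default_region_tissue_params <- function(n_regions = 36, seed = 1,
                                         base = tissue_params(0.102, 0.130, 0.062, 0),
                                         sdlog = 0.03) {
  set.seed(seed + 1000L)
  lapply(seq_len(n_regions), function(r) {
    m <- exp(stats::rnorm(3, 0, sdlog))
    structure(list(K1 = base$K1 * m[1], k2 = base$k2 * m[2],
                   k3 = base$k3 * m[3], k4 = base$k4),
              class = "tissue_params")
  })
}

# low-uptake soft tissue surrounding the brain and carotids
soft_tissue_params <- function() tissue_params(0.030, 0.120, 0.010, 0)

#' Reduce one region's net uptake by an exact fraction
#'
#' Scales the region's `k3` by `(1 - reduction_fraction)` and rescales `K1`
#' so the analytic `Ki = K1*k3/(k2+k3)` drops by exactly
#' `reduction_fraction`; all other regions are untouched. This emulates a
#' focal hypometabolic (e.g. epileptogenic) region.
#'
#' @param region_params List of [tissue_params] as from
#'   [default_region_tissue_params()].
#' @param region_id Region index to modify.
#' @param reduction_fraction Fractional Ki reduction in (0, 1).
#' @return The modified parameter list.
#' @export
inject_hypometabolic_region <- function(region_params, region_id,
                                        reduction_fraction) {
  stopifnot(reduction_fraction > 0, reduction_fraction < 1)
  if (region_id < 1 || region_id > length(region_params)) {
    stop(sprintf("unknown region %s", region_id), call. = FALSE)
  }
  p <- region_params[[region_id]]
  f <- 1 - reduction_fraction
  k3_new <- p$k3 * f
  # Ki ratio from the k3 change alone; K1 absorbs the remainder
  rho <- (f * (p$k2 + p$k3)) / (p$k2 + k3_new)
  p$k3 <- k3_new
  p$K1 <- p$K1 * f / rho
  region_params[[region_id]] <- p
  region_params
}

#' Gaussian point-spread-function blur
#'
#' Blurs a 3D volume with a stationary isotropic Gaussian of the given full
#' width at half maximum (`sigma = fwhm / (2*sqrt(2*log(2)))` per axis,
#' converted to voxels). Zero-padded borders; total activity of interior
#' structures is conserved to well under 0.1%.
#'
#' @param volume_3d 3D numeric array.
#' @param fwhm_mm FWHM in mm (>= 0; 0 is the identity).
#' @param voxel_mm Voxel size(s) in mm (scalar or length 3).
#' @return Blurred 3D array.
#' @export
apply_psf <- function(volume_3d, fwhm_mm, voxel_mm) {
  stopifnot(length(dim(volume_3d)) == 3L, fwhm_mm >= 0)
  if (fwhm_mm == 0) return(volume_3d)
  if (length(voxel_mm) == 1L) voxel_mm <- rep(voxel_mm, 3L)
  sigma_vox <- (fwhm_mm / (2 * sqrt(2 * log(2)))) / voxel_mm
  out <- cpp_gauss_blur3d(as.double(volume_3d), dim(volume_3d),
                          as.double(sigma_vox))
  array(out, dim = dim(volume_3d))
}

#' Add frame-duration-dependent Gaussian noise
#'
#' Per-voxel, per-frame additive Gaussian noise with
#' `SD = noise_scale * sqrt(max(value, 0) / duration_s)`, mimicking the
#' count-statistics behaviour of reconstructed PET (long frames are less
#' noisy); negative values are allowed, as in reconstructed images.
#'
#' @param dyn A [dynamic_volume].
#' @param noise_scale Non-negative magnitude; 0 is the identity.
#' @param seed Integer seed.
#' @return A noisy [dynamic_volume].
#' @export
add_noise <- function(dyn, noise_scale, seed = 1) {
  stopifnot(inherits(dyn, "dynamic_volume"), noise_scale >= 0)
  if (noise_scale == 0) return(dyn)
  set.seed(seed)
  d <- dim(dyn$data)
  out <- dyn$data
  for (f in seq_len(d[4])) {
    sd_f <- noise_scale * sqrt(pmax(out[, , , f], 0) / dyn$schedule$durations_s[f])
    out[, , , f] <- out[, , , f] + stats::rnorm(prod(d[1:3])) * sd_f
  }
  dynamic_volume(out, dyn$voxel_mm, dyn$schedule, dyn$affine)
}

#' Generate a synthetic dynamic FDG-PET study with known ground truth
#'
#' Voxel time-courses are frame-averaged model curves: carotid voxels carry
#' the plasma input, brain voxels their region's two-tissue curve, and the
#' remaining head volume a low-uptake soft-tissue curve. Each frame is then
#' PSF-blurred and noise is added. The returned truth object keeps the
#' pre-blur masks, the plasma parameters and curve, the per-region kinetic
#' parameters and each region's analytic Ki.
#'
#' @param spec A [phantom_spec].
#' @param plasma A [plasma_input_params] (default [default_plasma_params()]).
#' @param region_params Optional list of per-region [tissue_params]; defaults
#'   to [default_region_tissue_params()] drawn with the spec seed.
#' @param seed Seed for the noise draw (defaults to the spec seed).
#' @return List with `volume` (a [dynamic_volume]) and `truth` (list:
#'   `carotid_mask`, `region_labels`, `brain_mask`, `head_mask`,
#'   `plasma_params`, `region_params`, `ki_true` (1/min),
#'   `plasma_frames` ([tacurve]), `spec`).
#' @export
generate_phantom <- function(spec, plasma = default_plasma_params(),
                             region_params = NULL, seed = spec$seed) {
  stopifnot(inherits(spec, "phantom_spec"))
  geom <- phantom_geometry(spec)
  labels <- phantom_parcellation(spec, geom)
  R <- spec$region_count
  if (is.null(region_params)) {
    region_params <- default_region_tissue_params(R, seed = spec$seed)
  }
  if (length(region_params) < R) {
    stop(sprintf("need tissue parameters for %d regions, got %d",
                 R, length(region_params)), call. = FALSE)
  }
  sched <- spec$schedule
  dt <- 0.5
  t_fine <- seq(0, total_duration(sched) + dt, by = dt)
  cp <- feng_plasma(t_fine, plasma)
  cp_f <- frame_average_grid(cp, dt, sched)
  soft <- soft_tissue_params()
  curves <- rbind(
    frame_average_grid(two_tissue_from_cp(cp, soft, dt), dt, sched),
    t(vapply(region_params[seq_len(R)], function(p)
      frame_average_grid(two_tissue_from_cp(cp, p, dt), dt, sched),
      numeric(n_frames(sched)))))

  d <- spec$grid_shape
  # per-voxel curve index: 0 none, 1 soft tissue, 1+r region r, R+2 blood
  src <- array(0L, dim = d)
  src[geom$head] <- 1L
  src[labels$data > 0] <- 1L + labels$data[labels$data > 0]
  src[geom$carotid] <- R + 2L
  lut <- rbind(0, curves, cp_f)  # (R+3) x nframes, row 1 = background

  nf <- n_frames(sched)
  data <- array(0, dim = c(d, nf))
  blur <- spec$psf_fwhm_mm > 0
  for (f in seq_len(nf)) {
    vol <- array(lut[src + 1L, f], dim = d)
    if (blur) vol <- apply_psf(vol, spec$psf_fwhm_mm, spec$voxel_mm)
    data[, , , f] <- vol
  }
  dyn <- dynamic_volume(data, rep(spec$voxel_mm, 3), sched)
  if (spec$noise_scale > 0) dyn <- add_noise(dyn, spec$noise_scale, seed = seed)

  truth <- list(
    carotid_mask = mask3d(geom$carotid),
    region_labels = labels,
    brain_mask = mask3d(geom$brain),
    head_mask = mask3d(geom$head),
    plasma_params = plasma,
    region_params = region_params,
    ki_true = vapply(region_params[seq_len(R)], ki_analytic, numeric(1)),
    plasma_frames = tacurve(cp_f, sched$mid_s, label = "plasma"),
    spec = spec)
  list(volume = dyn, truth = truth)
}
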