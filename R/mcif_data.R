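#' Synthesize IDIF/MCIF training pairs from the kinetic forward model
#'
#' Draws random but physiologic parameter sets — plasma shape jittered
#' log-normally around [default_plasma_params()], gray-matter-like tissue
#' rates, blood recovery `rb ~ U(0.6, 0.9)` with complementary
#' tissue-to-blood spillover `st = 1 - rb` (a measured carotid voxel fully
#' covered by blood and tissue under a mass-preserving PSF is a convex
#' combination of the two), and a small blood-to-tissue spillover
#' `sb ~ U(0.02, 0.10)` with `rt = 1 - sb` — and generates frame-averaged
#' IDIF, adjacent-tissue and true plasma (MCIF) curves. Optional
#' frame-duration-dependent measurement noise can be added to the measured
#' pair. Sequences are min-max normalized by each sample's IDIF scale, the
#' convention MCIF-net trains under.
#'
#' @param n Number of pairs.
#' @param schedule A [frame_schedule] (default the 38-frame protocol).
#' @param seed Integer seed.
#' @param noise_frac Fractional noise level on the measured curves: per
#'   frame SD = `noise_frac * peak(idif) * sqrt(10 / duration_s)` (default
#'   0, noise-free).
#' @param dt Fine-grid spacing (s) for the kinetic model.
#' @return List: `X` (n x T normalized IDIF), `Y` (n x T MCIF on the same
#'   per-sample IDIF scale), `idif`, `tissue`, `mcif` (n x T matrices in
#'   Bq/cc), `scales` (n x 2 min/max of each IDIF), `meta` (data.frame with
#'   rb, st, sb, rt and the tissue rates and true Ki per sample).
#' @export
synthesize_mcif_pairs <- function(n, schedule = default_frame_schedule(),
                                  seed = 1, noise_frac = 0, dt = 0.5) {
  set.seed(seed)
  Tn <- n_frames(schedule)
  X <- Y <- IDIF <- TIS <- MCIF <- matrix(0, n, Tn)
  scales <- matrix(0, n, 2, dimnames = list(NULL, c("min", "max")))
  meta <- data.frame(rb = numeric(n), st = numeric(n), sb = numeric(n),
                     rt = numeric(n), K1 = numeric(n), k2 = numeric(n),
                     k3 = numeric(n), ki_true = numeric(n))
  base <- default_plasma_params()
  for (i in seq_len(n)) {
    jit <- exp(stats::rnorm(6, 0, 0.15))
    plasma <- plasma_input_params(
      A1 = base$A1 * jit[1], A2 = base$A2 * jit[2], A3 = base$A3 * jit[3],
      lambda1 = base$lambda1 * jit[4],
      lambda2 = base$lambda2 * jit[5],
      lambda3 = min(base$lambda3 * jit[6], 0.9 * base$lambda2 * jit[5]),
      tau = stats::runif(1, 10, 40))
    tj <- exp(stats::rnorm(3, 0, 0.15))
    tis <- structure(list(K1 = 0.102 / 60 * tj[1], k2 = 0.130 / 60 * tj[2],
                          k3 = 0.062 / 60 * tj[3], k4 = 0),
                     class = "tissue_params")
    rb <- stats::runif(1, 0.6, 0.9)
    sb <- stats::runif(1, 0.02, 0.10)
    mix <- mixing_params(rb = rb, st = 1 - rb, sb = sb, rt = 1 - sb)
    mm <- model_idif_and_tissue(plasma, tis, mix, schedule, dt = dt)
    idif <- mm$idif$values
    tissue <- mm$tissue$values
    if (noise_frac > 0) {
      sdv <- noise_frac * max(idif) * sqrt(10 / schedule$durations_s)
      idif <- idif + stats::rnorm(Tn) * sdv
      tissue <- tissue + stats::rnorm(Tn) * sdv
    }
    lo <- min(idif); hi <- max(idif)
    X[i, ] <- (idif - lo) / (hi - lo)
    Y[i, ] <- (mm$cp_frames$values - lo) / (hi - lo)
    IDIF[i, ] <- idif
    TIS[i, ] <- tissue
    MCIF[i, ] <- mm$cp_frames$values
    scales[i, ] <- c(lo, hi)
    meta[i, ] <- c(rb, 1 - rb, sb, 1 - sb, tis$K1 * 60, tis$k2 * 60,
                   tis$k3 * 60, ki_analytic(tis))
  }
  list(X = X, Y = Y, idif = IDIF, tissue = TIS, mcif = MCIF,
       scales = scales, meta = meta, schedule = schedule)
}

#' Crop a training pair to a box around the mask
#'
#' Extracts a `shape`-sized subvolume whose center is the mask centroid
#' plus an optional seeded jitter, clamped inside the grid — a cheap way to
#' focus network training on the informative neighbourhood while keeping
#' prediction fully convolutional on whole volumes.
#'
#' @param volume 3D array.
#' @param mask A [mask3d] aligned with `volume`.
#' @param shape Integer length-3 crop shape.
#' @param jitter_vox Maximum uniform jitter of the crop center (voxels).
#' @param seed Seed for the jitter draw.
#' @return List `volume`, `mask` of size `shape`.
#' @export
crop_around_mask <- function(volume, mask, shape, jitter_vox = 0, seed = 1) {
  stopifnot(inherits(mask, "mask3d"), all(dim(volume) == dim(mask$data)),
            all(shape <= dim(volume)))
  idx <- which(mask$data == 1L, arr.ind = TRUE)
  ctr <- if (nrow(idx) > 0) colMeans(idx) else (dim(volume) + 1) / 2
  if (jitter_vox > 0) {
    set.seed(seed)
    ctr <- ctr + stats::runif(3, -jitter_vox, jitter_vox)
  }
  start <- round(ctr - shape / 2)
  start <- pmin(pmax(start, 1), dim(volume) - shape + 1)
  ix <- lapply(1:3, function(i) start[i] + seq_len(shape[i]) - 1L)
  list(volume = volume[ix[[1]], ix[[2]], ix[[3]], drop = FALSE],
       mask = mask3d(mask$data[ix[[1]], ix[[2]], ix[[3]], drop = FALSE]))
}

#' Generate phantom subjects for segmentation benchmarks
#'
#' Each subject is an independently seeded phantom with its own anatomy
#' (carotid separation, radius and extent drawn per subject) and kinetics;
#' the network input is the bolus-transit frame chosen by
#' [select_reference_frame()], scaled to unit maximum, and the target is
#' the true carotid mask.
#'
#' @param n Number of subjects.
#' @param spec A [phantom_spec] template (per-subject seeds and anatomy
#'   jitter are derived from it).
#' @param seed Base seed.
#' @return List of items (`volume`, `mask`, `subject_id`, `frame_index`).
#' @export
phantom_segmentation_subjects <- function(n, spec = phantom_spec(), seed = 1) {
  lapply(seq_len(n), function(i) {
    sp <- spec
    sp$seed <- as.integer(seed + 101L * i)
    set.seed(sp$seed)
    sp$carotid_offset_mm <- spec$carotid_offset_mm + stats::runif(1, -2, 2)
    sp$carotid_radius_mm <- spec$carotid_radius_mm + stats::runif(1, -0.4, 0.4)
    sp$carotid_z_frac <- c(stats::runif(1, 0.08, 0.12), stats::runif(1, 0.26, 0.31))
    ph <- generate_phantom(sp)
    sel <- select_reference_frame(ph$volume)
    frame <- ph$volume$data[, , , sel$frame_index]
    list(volume = frame / max(frame), mask = ph$truth$carotid_mask,
         subject_id = paste0("s", i), frame_index = sel$frame_index)
  })
}
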