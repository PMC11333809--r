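#' Spatial containers: dynamic volumes, masks, region labels
#'
#' `dynamic_volume` holds a 4D activity grid `[x, y, z, frame]` in Bq/cc with
#' voxel spacing in mm, a voxel-to-world affine and an attached
#' [frame_schedule]. `mask3d` holds an aligned binary grid, `region_labels`
#' an aligned integer parcellation (0 = background, 1..R = super-regions).
#'
#' @param data 4D numeric array `[x, y, z, frame]` of activity (Bq/cc).
#' @param voxel_mm Numeric length-3 vector of positive voxel dimensions (mm).
#' @param schedule A [frame_schedule] whose frame count matches `dim(data)[4]`.
#' @param affine Optional 4x4 voxel-to-world matrix; defaults to a diagonal
#'   scaling by `voxel_mm`.
#' @return A `dynamic_volume` object.
#' @export
dynamic_volume <- function(data, voxel_mm, schedule, affine = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 4L,
            inherits(schedule, "frame_schedule"))
  voxel_mm <- as.numeric(voxel_mm)
  if (length(voxel_mm) == 1L) voxel_mm <- rep(voxel_mm, 3L)
  stopifnot(length(voxel_mm) == 3L, all(voxel_mm > 0))
  if (dim(data)[4] != n_frames(schedule)) {
    stop(sprintf("volume has %d frames but schedule has %d",
                 dim(data)[4], n_frames(schedule)), call. = FALSE)
  }
  if (!all(is.finite(data))) stop("activity values must be finite", call. = FALSE)
  if (is.null(affine)) {
    affine <- diag(c(voxel_mm, 1))
  }
  stopifnot(is.matrix(affine), all(dim(affine) == c(4L, 4L)))
  structure(list(data = data, voxel_mm = voxel_mm, affine = affine,
                 schedule = schedule),
            class = "dynamic_volume")
}

#' @export
print.dynamic_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("dynamic_volume: %dx%dx%d voxels x %d frames, voxel %s mm, %.0f s\n",
              d[1], d[2], d[3], d[4],
              paste(format(x$voxel_mm), collapse = "x"),
              total_duration(x$schedule)))
  invisible(x)
}

#' @rdname dynamic_volume
#' @param reference Optional `dynamic_volume` (or 3D dims) the mask must align
#'   with.
#' @export
mask3d <- function(data, reference = NULL) {
  stopifnot(is.array(data) || is.logical(data), length(dim(data)) == 3L)
  vals <- unique(as.vector(data))
  if (!all(vals %in% c(0, 1, TRUE, FALSE))) {
    stop("mask values must be binary (0/1); found other values", call. = FALSE)
  }
  data <- array(as.integer(data != 0), dim = dim(data))
  check_spatial_alignment(dim(data), reference, "mask")
  structure(list(data = data), class = "mask3d")
}

#' @rdname dynamic_volume
#' @export
region_labels <- function(data, reference = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  if (any(data < 0) || any(data != round(data))) {
    stop("region labels must be non-negative integers", call. = FALSE)
  }
  data <- array(as.integer(data), dim = dim(data))
  check_spatial_alignment(dim(data), reference, "region labels")
  structure(list(data = data, n_regions = max(data)), class = "region_labels")
}

check_spatial_alignment <- function(dims, reference, what) {
  if (is.null(reference)) return(invisible(TRUE))
  ref_dims <- if (inherits(reference, "dynamic_volume")) dim(reference$data)[1:3]
              else if (is.numeric(reference)) reference[1:3]
              else dim(reference)[1:3]
  if (!all(dims == ref_dims)) {
    stop(sprintf("%s grid %s does not match parent grid %s", what,
                 paste(dims, collapse = "x"), paste(ref_dims, collapse = "x")),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Time-activity curves
#'
#' Per-frame activity (Bq/cc) paired with frame mid-times in seconds.
#'
#' @param values Numeric vector of per-frame activity (Bq/cc).
#' @param times_s Strictly increasing numeric vector of frame mid-times (s).
#' @param label Optional character label (e.g. `"IDIF"`, `"tissue"`, `"MCIF"`).
#' @return A `tacurve` object.
#' @export
tacurve <- function(values, times_s, label = NULL) {
  values <- as.numeric(values)
  times_s <- as.numeric(times_s)
  stopifnot(length(values) == length(times_s))
  if (length(times_s) > 1 && any(diff(times_s) <= 0)) {
    stop("frame mid-times must be strictly increasing", call. = FALSE)
  }
  structure(list(values = values, times_s = times_s, label = label),
            class = "tacurve")
}

#' @export
print.tacurve <- function(x, ...) {
  cat(sprintf("tacurve%s: %d frames, peak %.4g Bq/cc at %.0f s\n",
              if (is.null(x$label)) "" else paste0(" [", x$label, "]"),
              length(x$values), max(x$values), x$times_s[which.max(x$values)]))
  invisible(x)
}

#' Mean time-activity curve over a mask
#'
#' Computes the per-frame mean of voxel values inside a binary mask — the
#' image-derived input function when the mask covers the internal carotid
#' arteries.
#'
#' @param dyn A [dynamic_volume].
#' @param mask A [mask3d] aligned with `dyn` and containing at least one voxel.
#' @param label Optional label for the returned curve.
#' @return A [tacurve].
#' @export
extract_tac <- function(dyn, mask, label = NULL) {
  stopifnot(inherits(dyn, "dynamic_volume"), inherits(mask, "mask3d"))
  check_spatial_alignment(dim(mask$data), dyn, "mask")
  idx <- which(mask$data != 0L)
  if (length(idx) == 0L) stop("mask is empty", call. = FALSE)
  nf <- n_frames(dyn$schedule)
  nv <- prod(dim(dyn$data)[1:3])
  flat <- matrix(dyn$data, nrow = nv, ncol = nf)
  tacurve(colMeans(flat[idx, , drop = FALSE]), dyn$schedule$mid_s, label = label)
}
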