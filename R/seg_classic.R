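#' Classical carotid segmentation by thresholding and island analysis
#'
#' Reproduces the semi-automated procedure: binarize the bolus-transit frame
#' at an intensity threshold, label 26-connected components ("islands"),
#' drop components below a minimum size, keep the `keep_k` largest (the two
#' carotids) and merge them into one mask.
#'
#' @param frame_3d 3D array (the selected bolus-transit frame).
#' @param intensity_threshold Absolute intensity cutoff (voxels `>=`
#'   threshold are foreground).
#' @param min_component_voxels Components smaller than this are discarded
#'   (default 10).
#' @param keep_k Number of largest components to keep (default 2).
#' @return A [mask3d]; empty (with a warning) if nothing survives.
#' @export
threshold_islands_segment <- function(frame_3d, intensity_threshold,
                                      min_component_voxels = 10, keep_k = 2) {
  stopifnot(length(dim(frame_3d)) == 3L, is.finite(intensity_threshold))
  bin <- array(as.integer(frame_3d >= intensity_threshold), dim = dim(frame_3d))
  if (!any(bin == 1L)) {
    warning("no voxels at or above the threshold; returning an empty mask")
    return(mask3d(bin))
  }
  lab <- cpp_label_components26(bin, dim(bin))
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_component_voxels)
  if (length(keep) == 0L) {
    warning("all components below the minimum size; returning an empty mask")
    return(mask3d(array(0L, dim = dim(frame_3d))))
  }
  # labels are assigned in scan order, so ties resolve to the component
  # whose first voxel has the lowest linear index
  keep <- keep[order(-sizes[keep], keep)]
  keep <- keep[seq_len(min(keep_k, length(keep)))]
  mask3d(array(as.integer(lab %in% keep), dim = dim(frame_3d)))
}

#' Keep only the k largest connected components of a mask
#'
#' Post-hoc cleanup of predicted masks: retains the `k` largest 26-connected
#' components (ties broken toward the component containing the lowest linear
#' voxel index), removing small spurious clusters away from the carotids.
#' Never increases the foreground count.
#'
#' @param mask A [mask3d].
#' @param k Number of components to keep (default 2). With fewer than `k`
#'   components the mask is returned unchanged.
#' @return A [mask3d].
#' @export
keep_largest_components <- function(mask, k = 2) {
  stopifnot(inherits(mask, "mask3d"))
  if (!any(mask$data == 1L)) return(mask)
  lab <- cpp_label_components26(mask$data, dim(mask$data))
  sizes <- tabulate(lab[lab > 0L])
  if (length(sizes) <= k) return(mask)
  keep <- order(-sizes, seq_along(sizes))[seq_len(k)]
  mask3d(array(as.integer(lab %in% keep), dim = dim(mask$data)))
}
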