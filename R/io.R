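#' Read and write NIfTI volumes, curve CSVs and sidecar configs
#'
#' NIfTI-1 stores no per-frame timing, so 4D volumes travel with a sidecar
#' YAML config carrying the run-length frame schedule (see
#' [parse_frame_schedule()]). Masks and region labels round-trip bit-exactly
#' as integer NIfTI; activity volumes round-trip within float tolerance.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param schedule A [frame_schedule] matching the file's fourth dimension.
#' @return `read_nifti_4d` returns a [dynamic_volume].
#' @name nifti_io
NULL

#' @rdname nifti_io
#' @export
read_nifti_4d <- function(path, schedule) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 4L) {
    stop(sprintf("'%s' is %dD, expected a 4D dynamic volume",
                 path, length(dim(arr))), call. = FALSE)
  }
  pix <- attr(img, "pixdim")
  if (is.null(pix)) pix <- RNifti::pixdim(img)
  dynamic_volume(arr, voxel_mm = abs(pix[1:3]), schedule = schedule,
                 affine = unclass(RNifti::xform(img)))
}

#' @rdname nifti_io
#' @param vol A [dynamic_volume].
#' @export
write_nifti_4d <- function(vol, path) {
  stopifnot(inherits(vol, "dynamic_volume"))
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- c(vol$voxel_mm, 1)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname nifti_io
#' @param reference Optional grid to validate alignment against.
#' @export
read_mask <- function(path, reference = NULL) {
  arr <- as.array(RNifti::readNifti(path))
  if (length(dim(arr)) != 3L) stop("mask file must be 3D", call. = FALSE)
  mask3d(arr, reference = reference)
}

#' @rdname nifti_io
#' @param mask A [mask3d].
#' @param voxel_mm Voxel spacing written to the header.
#' @export
write_mask <- function(mask, path, voxel_mm = c(1, 1, 1)) {
  stopifnot(inherits(mask, "mask3d"))
  img <- RNifti::asNifti(array(as.integer(mask$data), dim = dim(mask$data)))
  RNifti::pixdim(img) <- voxel_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname nifti_io
#' @export
read_region_labels <- function(path, reference = NULL) {
  arr <- as.array(RNifti::readNifti(path))
  if (length(dim(arr)) != 3L) stop("region-label file must be 3D", call. = FALSE)
  region_labels(round(arr), reference = reference)
}

#' @rdname nifti_io
#' @param labels A [region_labels].
#' @export
write_region_labels <- function(labels, path, voxel_mm = c(1, 1, 1)) {
  stopifnot(inherits(labels, "region_labels"))
  img <- RNifti::asNifti(labels$data)
  RNifti::pixdim(img) <- voxel_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read/write time-activity curves as CSV
#'
#' CSV columns: `frame_index` (1-based), `mid_time_s`, `value` (Bq/cc).
#'
#' @param tac A [tacurve].
#' @param path Output CSV path.
#' @export
write_tac_csv <- function(tac, path) {
  stopifnot(inherits(tac, "tacurve"))
  utils::write.csv(
    data.frame(frame_index = seq_along(tac$values),
               mid_time_s = tac$times_s,
               value = tac$values),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tac_csv
#' @param label Optional label attached to the curve on read.
#' @export
read_tac_csv <- function(path, label = NULL) {
  df <- utils::read.csv(path)
  need <- c("mid_time_s", "value")
  if (!all(need %in% names(df))) {
    stop("curve CSV must have columns mid_time_s and value", call. = FALSE)
  }
  tacurve(df$value, df$mid_time_s, label = label)
}

#' Read/write a frame schedule as a sidecar YAML config
#'
#' @param schedule A [frame_schedule].
#' @param path YAML path.
#' @export
write_schedule_yaml <- function(schedule, path) {
  yaml::write_yaml(list(frame_schedule = format_frame_schedule(schedule)), path)
  invisible(path)
}

#' @rdname write_schedule_yaml
#' @export
read_schedule_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$frame_schedule)) {
    stop("sidecar config lacks a 'frame_schedule' entry", call. = FALSE)
  }
  parse_frame_schedule(cfg$frame_schedule)
}
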