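#' Configuration for the end-to-end quantification pipeline
#'
#' Validates and normalizes the options steering [run_pipeline()]:
#' phantom simulation (or paths to existing data), motion correction,
#' bolus-frame selection, segmentation mode, MCIF recovery method, Patlak
#' t* and the z-score cutoff. Unknown keys are rejected.
#'
#' @param phantom A [phantom_spec] to simulate, or `NULL` when `volume` is
#'   given.
#' @param volume Optional [dynamic_volume] input (with `carotid_mask`,
#'   `region_labels`, `brain_mask` supplied alongside unless segmentation
#'   is run).
#' @param carotid_mask,region_labels,brain_mask Optional inputs for
#'   non-phantom runs.
#' @param motion_correct Run rigid motion correction (default TRUE).
#' @param seg_mode `"classic"` (threshold/islands), `"unet"` (requires
#'   `unet_model`), or `"truth"` (phantom ground-truth mask).
#' @param unet_model Optional trained `unet_model` for `seg_mode = "unet"`.
#' @param threshold_frac Classic-mode threshold as a fraction of the
#'   selected frame's maximum (default 0.5).
#' @param mcif_method `"fit"` (optimizer, default) or `"net"` (requires
#'   `mcif_model`).
#' @param mcif_model Optional trained `mcif_net_model`.
#' @param n_starts Optimizer starts for [fit_mcif()] (default 6).
#' @param t_star_s Patlak linear-phase onset (default 1200 s).
#' @param z_cutoff Hypometabolism flagging threshold (default -2).
#' @param shell_inner_vox,shell_outer_vox Dilation radii (voxels) bounding
#'   the carotid-adjacent tissue shell used as the spillover tissue curve.
#' @param seed Global seed.
#' @param out_dir Optional directory for stage artifacts and provenance.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(phantom = phantom_spec(), volume = NULL,
                            carotid_mask = NULL, region_labels = NULL,
                            brain_mask = NULL, motion_correct = TRUE,
                            seg_mode = c("classic", "unet", "truth"),
                            unet_model = NULL, threshold_frac = 0.5,
                            mcif_method = c("fit", "net"), mcif_model = NULL,
                            n_starts = 6, t_star_s = 1200, z_cutoff = -2,
                            shell_inner_vox = 2, shell_outer_vox = 5,
                            seed = 1, out_dir = NULL) {
  seg_mode <- match.arg(seg_mode)
  mcif_method <- match.arg(mcif_method)
  if (is.null(phantom) && is.null(volume)) {
    stop("config error: provide a phantom spec or an input volume", call. = FALSE)
  }
  if (seg_mode == "unet" && is.null(unet_model)) {
    stop("config error: seg_mode 'unet' requires a trained unet_model", call. = FALSE)
  }
  if (mcif_method == "net" && is.null(mcif_model)) {
    stop("config error: mcif_method 'net' requires a trained mcif_model", call. = FALSE)
  }
  if (seg_mode == "truth" && is.null(phantom) && is.null(carotid_mask)) {
    stop("config error: seg_mode 'truth' needs a phantom or a supplied mask",
         call. = FALSE)
  }
  structure(list(phantom = phantom, volume = volume,
                 carotid_mask = carotid_mask, region_labels = region_labels,
                 brain_mask = brain_mask,
                 motion_correct = isTRUE(motion_correct), seg_mode = seg_mode,
                 unet_model = unet_model, threshold_frac = threshold_frac,
                 mcif_method = mcif_method, mcif_model = mcif_model,
                 n_starts = n_starts, t_star_s = t_star_s,
                 z_cutoff = z_cutoff, shell_inner_vox = shell_inner_vox,
                 shell_outer_vox = shell_outer_vox, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

# tissue shell around the carotid mask (between two dilation radii),
# restricted to the z-slab the vessels occupy so the sampled tissue is the
# vessels' own surroundings rather than structures above or below them
carotid_tissue_shell <- function(mask, inner = 2, outer = 5) {
  d <- dim(mask$data)
  outer_m <- cpp_dilate3d(mask$data, d, outer)
  inner_m <- cpp_dilate3d(mask$data, d, inner)
  shell <- array(as.integer(outer_m == 1L & inner_m == 0L), dim = d)
  zs <- which(apply(mask$data, 3, sum) > 0)
  if (length(zs) > 0) {
    keep <- seq(min(zs), max(zs))
    shell[, , setdiff(seq_len(d[3]), keep)] <- 0L
  }
  if (!any(shell == 1L)) stop("empty tissue shell around the carotid mask",
                              call. = FALSE)
  mask3d(shell)
}

#' Run the four-phase quantification pipeline end to end
#'
#' Phases: (1) preprocessing — phantom simulation or data loading, rigid
#' motion correction, bolus-frame selection; (2) carotid segmentation;
#' (3) IDIF extraction and MCIF recovery (optimizer fit or recurrent
#' network); (4) Patlak Ki map, regional z-scores and hypometabolism
#' flags. With a fixed seed the whole run is deterministic. When
#' `config$out_dir` is set each stage writes its artifact plus a JSON
#' provenance record.
#'
#' @param config A [pipeline_config].
#' @return List: `report` (regional z-score data.frame), `frame_index`,
#'   `carotid_mask`, `idif`, `tissue`, `mcif`, `mcif_fit` (when fitted),
#'   `ki`, `dice_vs_truth` (phantom runs), `truth` (phantom runs),
#'   `provenance`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  prov <- list(seed = config$seed, seg_mode = config$seg_mode,
               mcif_method = config$mcif_method, t_star_s = config$t_star_s,
               package_version = as.character(utils::packageVersion("dynpet")))
  truth <- NULL
  if (!is.null(config$phantom)) {
    sp <- config$phantom
    sp$seed <- config$seed
    ph <- generate_phantom(sp, seed = config$seed)
    dyn <- ph$volume
    truth <- ph$truth
    labels <- truth$region_labels
    brain <- truth$brain_mask
  } else {
    dyn <- config$volume
    labels <- config$region_labels
    brain <- config$brain_mask
  }
  if (is.null(labels) || is.null(brain)) {
    stop("data error: region labels and brain mask are required", call. = FALSE)
  }

  if (config$motion_correct) {
    ref <- reference_from_early_frames(dyn, n_frames = min(14, dim(dyn$data)[4]))
    mc <- motion_correct(dyn, ref)
    dyn <- mc$volume
    prov$motion_transforms <- lapply(mc$transforms, unclass)
  }

  sel <- select_reference_frame(dyn)
  frame <- dyn$data[, , , sel$frame_index]

  mask <- switch(config$seg_mode,
    classic = {
      m <- threshold_islands_segment(frame,
                                     intensity_threshold = config$threshold_frac * max(frame),
                                     min_component_voxels = 10, keep_k = 2)
      keep_largest_components(m, k = 2)
    },
    unet = {
      m <- predict_mask(config$unet_model, frame / max(frame))
      keep_largest_components(m, k = 2)
    },
    truth = {
      if (!is.null(truth)) truth$carotid_mask else config$carotid_mask
    })
  if (!any(mask$data == 1L)) {
    stop("numerical failure: carotid segmentation produced an empty mask",
         call. = FALSE)
  }

  idif <- extract_tac(dyn, mask, label = "IDIF")
  shell <- carotid_tissue_shell(mask, config$shell_inner_vox,
                                config$shell_outer_vox)
  tissue <- extract_tac(dyn, shell, label = "tissue")

  fit <- NULL
  if (config$mcif_method == "fit") {
    fit <- fit_mcif(idif, tissue, dyn$schedule, n_starts = config$n_starts,
                    seed = config$seed)
    mcif <- fit$mcif
  } else {
    mcif <- predict_mcif(config$mcif_model, idif)
  }

  ki <- ki_map(dyn, mcif, t_star_s = config$t_star_s, brain_mask = brain)
  report <- regional_zscores(ki, labels, z_cutoff = config$z_cutoff)

  out <- list(report = report, frame_index = sel$frame_index,
              carotid_mask = mask, idif = idif, tissue = tissue,
              mcif = mcif, mcif_fit = fit, ki = ki, truth = truth,
              provenance = prov)
  if (!is.null(truth)) {
    out$dice_vs_truth <- dice_coefficient(truth$carotid_mask,
                                          mask$data * 1.0)
  }
  if (!is.null(config$out_dir)) write_pipeline_artifacts(out, dyn, config)
  out
}

write_pipeline_artifacts <- function(out, dyn, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(x) file.path(config$out_dir, x)
  write_nifti_4d(dyn, fp("volume.nii.gz"))
  write_schedule_yaml(dyn$schedule, fp("schedule.yaml"))
  write_mask(out$carotid_mask, fp("carotid_mask.nii.gz"), dyn$voxel_mm)
  write_tac_csv(out$idif, fp("idif.csv"))
  write_tac_csv(out$mcif, fp("mcif.csv"))
  ki_img <- RNifti::asNifti(out$ki)
  RNifti::pixdim(ki_img) <- dyn$voxel_mm
  RNifti::writeNifti(ki_img, fp("ki.nii.gz"))
  utils::write.csv(out$report, fp("report.csv"), row.names = FALSE)
  if (!is.null(out$truth)) {
    write_region_labels(out$truth$region_labels, fp("regions.nii.gz"),
                        dyn$voxel_mm)
  }
  jsonlite::write_json(out$provenance, fp("provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}
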