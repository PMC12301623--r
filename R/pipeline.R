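# Pipeline driver: validated configuration, staged execution with a run
# manifest, and per-stage seed substreams derived from one global seed.

pipeline_defaults <- function() {
  list(
    phantom = list(voxel_mm = 0.114, lateral_mm = 6.27, length_mm = 25.08,
                   birefringence_sign = -1, dn_noise_sd = 0),
    trajectory = list(entry_mm = c(3.135, 3.135, 0), length_mm = 23),
    acquisition = list(alines_per_frame = 512, imaging_depth_mm = 1.5,
                       spectral_bins = 1, spectral_system_deg = 0,
                       speckle = TRUE, detector_noise_sd = 0.1),
    catheter = list(sheath_retardance = 0.3, sheath_orientation_deg = 0,
                    offset_amplitude_deg = 20, drift_deg_total = 10),
    mri = list(voxel_mm = 0.57, noise_sd = 0.02),
    reconstruction = list(filter_axial_sigma = 1, filter_lateral_sigma = 2,
                          dop_threshold = 0.7, ret_floor_deg100 = 5,
                          compensate = TRUE, offset_smooth_window = 15),
    carpet = list(depth_offset_um = 300, band_px = 2, analysis_length_mm = 21),
    barcode = list(min_frac = 0.25),
    seed = 1L
  )
}

#' Assemble and validate a pipeline configuration
#'
#' Nested configuration for the full phantom-to-barcode pipeline. Unknown
#' keys (at either level) are rejected; numeric fields are validated by the
#' constructors of the stage they configure.
#'
#' @param ... Named sections overriding the defaults (`phantom`,
#'   `trajectory`, `acquisition`, `catheter`, `mri`, `reconstruction`,
#'   `carpet`, `barcode`, `seed`).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  user <- list(...)
  defs <- pipeline_defaults()
  bad <- setdiff(names(user), names(defs))
  if (length(bad)) stop("unknown configuration section(s): ", paste(bad, collapse = ", "))
  cfg <- defs
  for (nm in names(user)) {
    if (nm == "seed") {
      cfg$seed <- as.integer(user$seed)
      next
    }
    sec <- user[[nm]]
    if (!is.list(sec)) stop("section '", nm, "' must be a list")
    known <- switch(nm,
      phantom = names(formals(phantom_config)),
      trajectory = names(formals(trajectory)),
      acquisition = names(formals(acq_config)),
      catheter = names(formals(catheter_model)),
      mri = c("voxel_mm", "noise_sd", "intensity_map"),
      reconstruction = names(formals(recon_options)),
      carpet = c("depth_offset_um", "band_px", "analysis_length_mm", "display_max"),
      barcode = c("min_frac"))
    badk <- setdiff(names(sec), known)
    if (length(badk)) {
      stop("unknown key(s) in section '", nm, "': ", paste(badk, collapse = ", "))
    }
    cfg[[nm]] <- utils::modifyList(cfg[[nm]], sec)
  }
  structure(cfg, class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file path.
#' @return A validated `pipeline_config`.
#' @export
load_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("missing configuration file: ", path)
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

# deterministic per-stage substream below 2^31
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

pipeline_paths <- function(outdir) {
  list(phantom = file.path(outdir, "phantom.rds"),
       pullback = file.path(outdir, "pullback.rds"),
       biref = file.path(outdir, "biref.rds"),
       carpet = file.path(outdir, "carpet.rds"),
       mri = file.path(outdir, "mri.nii.gz"),
       roi = file.path(outdir, "roi.rds"),
       barcodes = file.path(outdir, "barcodes.rds"),
       barcodes_json = file.path(outdir, "barcodes.json"),
       compare = file.path(outdir, "compare.json"),
       render = file.path(outdir, "carpet_oa.png"),
       carpet_tiff = file.path(outdir, "carpet_ret.tif"),
       manifest = file.path(outdir, "manifest.json"))
}

require_inputs <- function(paths) {
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("missing input(s) for this stage: ", paste(missing, collapse = ", "),
         " (run the producing stage first)")
  }
}

#' Run one pipeline stage
#'
#' Stages: `phantom`, `simulate`, `reconstruct`, `carpet`, `mri-roi`,
#' `barcode`, `compare`, `render`. Each stage reads its inputs from
#' `outdir` (failing with a missing-input error when a prerequisite stage
#' has not run), writes its outputs there, and returns a manifest entry
#' with parameter snapshot and input/output digests.
#'
#' @param name Stage name.
#' @param config A [pipeline_config()].
#' @param outdir Working directory for stage files.
#' @return The manifest entry, invisibly.
#' @export
run_stage <- function(name, config, outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  p <- pipeline_paths(outdir)
  t0 <- Sys.time()
  inputs <- character(0)
  outputs <- character(0)
  sd <- stage_seed(config$seed, name)
  switch(name,
    "phantom" = {
      ph <- build_dbs_phantom(do.call(phantom_config, config$phantom), seed = sd)
      write_stage_rds(ph, p$phantom)
      outputs <- p$phantom
    },
    "simulate" = {
      inputs <- p$phantom
      require_inputs(inputs)
      ph <- read_stage_rds(p$phantom, "tissue_phantom")
      traj <- do.call(trajectory, config$trajectory)
      raw <- simulate_pullback(ph, traj,
                               do.call(catheter_model, config$catheter),
                               do.call(acq_config, config$acquisition),
                               seed = sd)
      write_stage_rds(raw, p$pullback)
      outputs <- p$pullback
    },
    "reconstruct" = {
      inputs <- p$pullback
      require_inputs(inputs)
      raw <- read_stage_rds(p$pullback, "pullback_raw")
      lb <- reconstruct_pullback(raw, do.call(recon_options, config$reconstruction))
      write_stage_rds(lb, p$biref)
      outputs <- p$biref
    },
    "carpet" = {
      inputs <- p$biref
      require_inputs(inputs)
      lb <- read_stage_rds(p$biref, "local_biref_map")
      cv <- extract_carpet(lb, depth_offset_um = config$carpet$depth_offset_um,
                           band_px = config$carpet$band_px)
      write_stage_rds(cv, p$carpet)
      write_carpet_tiff(cv, p$carpet_tiff, "ret")
      outputs <- c(p$carpet, p$carpet_tiff)
    },
    "mri-roi" = {
      inputs <- p$phantom
      require_inputs(inputs)
      ph <- read_stage_rds(p$phantom, "tissue_phantom")
      mri <- render_mri(ph, voxel_mm = config$mri$voxel_mm,
                        intensity_map = config$mri$intensity_map,
                        noise_sd = config$mri$noise_sd, seed = sd)
      write_mri_nifti(mri, p$mri)
      traj <- do.call(trajectory, config$trajectory)
      roi <- extract_roi_cube(mri, traj,
                              length_mm = config$carpet$analysis_length_mm)
      unf <- unfold_perimeter(roi)
      write_stage_rds(list(roi = roi, unfolded = unf), p$roi)
      outputs <- c(p$mri, p$roi)
    },
    "barcode" = {
      inputs <- c(p$carpet, p$roi)
      require_inputs(inputs)
      cv <- read_stage_rds(p$carpet, "carpet_view")
      ro <- read_stage_rds(p$roi)
      bc_ps <- binarize(longitudinal_profile(cv, min_frac = config$barcode$min_frac))
      bc_mri <- binarize(longitudinal_profile(ro$unfolded, source = "mri",
                                              min_frac = config$barcode$min_frac))
      write_stage_rds(list(psoct = bc_ps, mri = bc_mri), p$barcodes)
      write_report_json(list(
        psoct = list(code = bc_ps$code, centers = bc_ps$centers,
                     threshold = bc_ps$threshold,
                     row_spacing_mm = bc_ps$row_spacing_mm),
        mri = list(code = bc_mri$code, centers = bc_mri$centers,
                   threshold = bc_mri$threshold,
                   row_spacing_mm = bc_mri$row_spacing_mm)), p$barcodes_json)
      outputs <- c(p$barcodes, p$barcodes_json)
    },
    "compare" = {
      inputs <- p$barcodes
      require_inputs(inputs)
      bc <- read_stage_rds(p$barcodes)
      rep <- compare_barcodes(bc$psoct, bc$mri)
      write_report_json(list(agreement = rep$agreement,
                             dice = as.list(rep$dice),
                             transitions_psoct_mm = rep$transitions_psoct_mm,
                             transitions_mri_mm = rep$transitions_mri_mm,
                             n = rep$n), p$compare)
      outputs <- p$compare
    },
    "render" = {
      inputs <- p$carpet
      require_inputs(inputs)
      cv <- read_stage_rds(p$carpet, "carpet_view")
      dm <- config$carpet$display_max
      if (is.null(dm)) dm <- 30
      write_render_png(render_oa_hsv(cv, display_max = dm), p$render)
      outputs <- p$render
    },
    stop("unknown stage: ", name)
  )
  entry <- list(stage = name, seed = sd,
                started = format(t0, "%Y-%m-%dT%H:%M:%OS3"),
                elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
                inputs = as.list(tools::md5sum(inputs)),
                outputs = as.list(tools::md5sum(outputs)))
  invisible(entry)
}

#' Run the full pipeline
#'
#' Executes all stages in order (`phantom`, `simulate`, `reconstruct`,
#' `carpet`, `mri-roi`, `barcode`, `compare`, `render`) and writes a run
#' manifest (configuration snapshot, per-stage seeds, file digests,
#' timings) to `manifest.json` in `outdir`.
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory.
#' @param stages Stage subset to run, in order.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir,
                         stages = c("phantom", "simulate", "reconstruct",
                                    "carpet", "mri-roi", "barcode", "compare",
                                    "render")) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  entries <- lapply(stages, function(s) run_stage(s, config, outdir))
  manifest <- list(version = as.character(utils::packageVersion("psoct")),
                   seed = config$seed,
                   config = unclass(config),
                   stages = entries)
  write_report_json(manifest, pipeline_paths(outdir)$manifest)
  invisible(manifest)
}
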