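# File I/O: NIfTI-1 for MRI volumes, RDS containers for pullbacks and maps,
# 16-bit TIFF / PNG for carpet exports, JSON for reports, YAML for configs.

#' Write an MRI volume as NIfTI-1
#'
#' @param mri An `mri_volume`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return The path, invisibly.
#' @export
write_mri_nifti <- function(mri, path) {
  stopifnot(inherits(mri, "mri_volume"))
  img <- RNifti::asNifti(mri$data)
  RNifti::pixdim(img) <- mri$voxel_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read an MRI volume from NIfTI-1
#'
#' @param path Input path.
#' @return An `mri_volume` with the voxel geometry from the header.
#' @export
read_mri_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  if (length(pd) < 3 || any(!is.finite(pd[1:3])) || any(pd[1:3] <= 0)) {
    stop("malformed NIfTI header: nonpositive pixdim")
  }
  structure(list(data = array(as.numeric(img), dim = dim(img)),
                 voxel_mm = as.numeric(pd[1:3]), origin_mm = c(0, 0, 0),
                 coverage = NULL),
            class = "mri_volume")
}

#' Serialize / restore pipeline objects
#'
#' Pullbacks, birefringence maps and other stage outputs are stored as R
#' native RDS containers.
#'
#' @param obj Object to store.
#' @param path File path.
#' @return `write_stage_rds`: the path, invisibly; `read_stage_rds`: the
#'   restored object.
#' @export
write_stage_rds <- function(obj, path) {
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname write_stage_rds
#' @param expect_class Optional class the restored object must have.
#' @export
read_stage_rds <- function(path, expect_class = NULL) {
  if (!file.exists(path)) stop("missing input file: ", path)
  obj <- readRDS(path)
  if (!is.null(expect_class) && !inherits(obj, expect_class)) {
    stop("file ", path, " does not contain a ", expect_class)
  }
  obj
}

#' Export a carpet plane as 16-bit TIFF
#'
#' @param carpet A `carpet_view`.
#' @param path Output path.
#' @param what One of "ret", "orientation", "intensity".
#' @param max_value Value mapped to the 16-bit maximum (defaults to the
#'   plane's finite maximum).
#' @return The scaling maximum, invisibly.
#' @export
write_carpet_tiff <- function(carpet, path, what = c("ret", "orientation", "intensity"),
                              max_value = NULL) {
  stopifnot(inherits(carpet, "carpet_view"))
  what <- match.arg(what)
  m <- switch(what, ret = carpet$ret_deg100, orientation = carpet$orientation_deg,
              intensity = carpet$intensity)
  m[!is.finite(m)] <- 0
  if (is.null(max_value)) max_value <- max(m, 1e-12)
  tiff::writeTIFF(pmin(pmax(m / max_value, 0), 1), path, bits.per.sample = 16)
  invisible(max_value)
}

#' Write an RGB rendering as PNG
#'
#' @param rgb RGB array `[rows, cols, 3]` in `[0, 1]`, e.g. from
#'   [render_oa_hsv()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_render_png <- function(rgb, path) {
  png::writePNG(pmin(pmax(rgb, 0), 1), path)
  invisible(path)
}

#' JSON report helpers
#'
#' @param x List to serialize.
#' @param path File path.
#' @return `write_report_json`: the path, invisibly; `read_report_json`:
#'   the parsed list.
#' @export
write_report_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_report_json
#' @export
read_report_json <- function(path) {
  if (!file.exists(path)) stop("missing input file: ", path)
  jsonlite::read_json(path, simplifyVector = TRUE)
}
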