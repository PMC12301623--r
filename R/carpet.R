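# En-face carpet views and the matching unfolded MRI region of interest.

#' Extract the unrolled en-face carpet view
#'
#' Samples the reconstructed local properties at a fixed depth into tissue
#' (default 300 um outside the catheter sheath), averaging over a +/-
#' `band_px` depth band: plain mean for retardance and intensity, circular
#' mean (period 180) for orientation. Rows are frames (longitudinal
#' position, one pitch per row), columns are A-line pairs (azimuth).
#'
#' @param lb A `local_biref_map` with absolute orientations (see
#'   [guide_star_correct()]).
#' @param depth_offset_um Sampling depth beyond the sheath outer boundary.
#' @param band_px Half-width of the depth averaging band in pixels.
#' @param min_valid_frac Minimum fraction of valid band pixels for a carpet
#'   pixel to stay unmasked.
#' @return A list of class `carpet_view` with matrices `[frame, pair]`:
#'   `ret_deg100`, `orientation_deg`, `intensity`, `mask`; plus geometry.
#' @export
extract_carpet <- function(lb, depth_offset_um = 300, band_px = 2,
                           min_valid_frac = 0.5) {
  stopifnot(inherits(lb, "local_biref_map"))
  if (is.null(lb$orientation_absolute_deg)) {
    stop("run guide_star_correct() before extracting the carpet")
  }
  meta <- lb$raw_meta
  pix <- lb$acq$axial_pixel_um
  d <- dim(lb$mask)
  tissue0 <- meta$n_pre + meta$n_sheath
  idx <- tissue0 + round(depth_offset_um / pix)
  band <- max(tissue0 + 1, idx - band_px):min(d[1], idx + band_px)
  if (idx > d[1] || idx <= tissue0) {
    stop("carpet depth offset outside the reconstructed depth range")
  }
  nf <- d[3]; np <- d[2]
  ret <- ori <- inten <- matrix(NA_real_, nf, np)
  msk <- matrix(FALSE, nf, np)
  for (f in seq_len(nf)) {
    m <- lb$mask[band, , f, drop = FALSE][, , 1]
    r <- lb$ret_deg100[band, , f, drop = FALSE][, , 1]
    o <- lb$orientation_absolute_deg[band, , f, drop = FALSE][, , 1]
    iv <- if (!is.null(lb$intensity)) lb$intensity[band, , f, drop = FALSE][, , 1] else
      matrix(NA_real_, length(band), np)
    for (p in seq_len(np)) {
      keep <- m[, p]
      msk[f, p] <- mean(keep) >= min_valid_frac
      inten[f, p] <- mean(iv[, p], na.rm = TRUE)
      if (any(keep)) {
        ret[f, p] <- mean(r[keep, p])
        ori[f, p] <- circ_mean_180(o[keep, p])
      } else {
        ret[f, p] <- mean(r[, p][is.finite(r[, p])])
        if (!is.finite(ret[f, p])) ret[f, p] <- 0
      }
    }
  }
  structure(list(ret_deg100 = ret, orientation_deg = ori, intensity = inten,
                 mask = msk, pitch_mm = meta$pitch_mm,
                 depth_offset_um = depth_offset_um,
                 pair_azimuth_deg = carpet_pair_azimuths(lb$acq)),
            class = "carpet_view")
}

carpet_pair_azimuths <- function(acq) {
  npair <- acq$alines_per_frame / 2
  dalpha <- 360 / acq$alines_per_frame
  (acq$start_azimuth_deg + (2 * seq_len(npair) - 1.5) * dalpha) %% 360
}

#' Extract the MRI region-of-interest cube along a trajectory
#'
#' A 5x5-voxel cross-section centered on the trajectory's voxel column (nine
#' central pixels covering the catheter path, sixteen perimeter pixels),
#' extended slice by slice from the cortical entry over the analysis length.
#'
#' @param mri An `mri_volume`.
#' @param traj A [trajectory()] (grid-axis aligned).
#' @param length_mm Analysis length along the trajectory (default 21 mm).
#' @return A list of class `roi_cube` with `cube` (`[5, 5, N]`),
#'   `slice_spacing_mm`, `n_slices`, `center_voxel`, `ring_span_mm`.
#' @export
extract_roi_cube <- function(mri, traj, length_mm = 21) {
  stopifnot(inherits(mri, "mri_volume"), inherits(traj, "trajectory"))
  d <- dim(mri$data)
  vx <- mri$voxel_mm
  spacing <- vx[3]
  n <- as.integer(ceiling(length_mm / spacing - 1e-9))
  i0 <- floor((traj$entry_mm[1] - mri$origin_mm[1]) / vx[1]) + 1L
  j0 <- floor((traj$entry_mm[2] - mri$origin_mm[2]) / vx[2]) + 1L
  k0 <- floor((traj$entry_mm[3] - mri$origin_mm[3]) / spacing) + 1L
  if (i0 - 2 < 1 || i0 + 2 > d[1] || j0 - 2 < 1 || j0 + 2 > d[2]) {
    stop("trajectory too close to the volume edge for the 5x5 window")
  }
  if (k0 < 1 || k0 + n - 1 > d[3]) stop("analysis length exceeds the volume extent")
  cube <- mri$data[(i0 - 2):(i0 + 2), (j0 - 2):(j0 + 2), k0:(k0 + n - 1), drop = FALSE]
  structure(list(cube = cube, slice_spacing_mm = spacing, n_slices = n,
                 center_voxel = c(i0, j0, k0),
                 ring_span_mm = 16 * max(vx[1], vx[2])),
            class = "roi_cube")
}

# perimeter path of the 5x5 cross-section: start at the ring pixel on the
# +first-axis from center, proceed counterclockwise; offsets are (axis1, axis2)
perimeter_offsets <- function() {
  cbind(
    c(2, 2, 2, 1, 0, -1, -2, -2, -2, -2, -2, -1, 0, 1, 2, 2),
    c(0, 1, 2, 2, 2, 2, 2, 1, 0, -1, -2, -2, -2, -2, -2, -1)
  )
}

#' Unfold the ROI cube perimeter into a 2-D map
#'
#' Reads the sixteen perimeter pixels of each slice in a fixed circular
#' order (start at the ring pixel on the +first-axis from the center, then
#' counterclockwise in the cross-section plane) into sixteen columns, so
#' that carpet azimuth 0 aligns with column 1.
#'
#' @param roi A `roi_cube`.
#' @return A list of class `unfolded_roi` with `data` (`[slice, 16]`),
#'   `slice_spacing_mm`, and the perimeter ordering metadata.
#' @export
unfold_perimeter <- function(roi) {
  stopifnot(inherits(roi, "roi_cube"))
  off <- perimeter_offsets()
  n <- roi$n_slices
  out <- matrix(NA_real_, n, 16)
  for (k in 1:16) {
    out[, k] <- roi$cube[3 + off[k, 1], 3 + off[k, 2], ]
  }
  structure(list(data = out, slice_spacing_mm = roi$slice_spacing_mm,
                 ordering = list(start = "+axis1", direction = "counterclockwise",
                                 offsets = off)),
            class = "unfolded_roi")
}

#' Longitudinal row-to-slice index map
#'
#' Maps each carpet row (one pitch per row) to the MRI slice containing its
#' longitudinal position, nearest-neighbor with no resampling: row `j`
#' (0-based, position `j * pitch` from the shared cortical-entry origin)
#' maps to slice `floor(position / slice spacing)` (0-based; slice centers
#' sit at `(i + 0.5) * spacing`). Returned indices are 1-based.
#'
#' @param carpet A `carpet_view` (or the number of rows).
#' @param roi An `unfolded_roi` / `roi_cube` (or the number of slices).
#' @param pitch_mm,slice_mm Spacings, taken from the objects when omitted.
#' @return A list of class `longitudinal_map` with `map` (1-based slice
#'   index per row) and `table` (row, position, slice).
#' @export
longitudinal_mapping <- function(carpet, roi, pitch_mm = NULL, slice_mm = NULL) {
  if (inherits(carpet, "carpet_view")) {
    n_rows <- nrow(carpet$ret_deg100)
    if (is.null(pitch_mm)) pitch_mm <- carpet$pitch_mm
  } else {
    n_rows <- as.integer(carpet)
  }
  if (inherits(roi, "unfolded_roi")) {
    n_slices <- nrow(roi$data)
    if (is.null(slice_mm)) slice_mm <- roi$slice_spacing_mm
  } else if (inherits(roi, "roi_cube")) {
    n_slices <- roi$n_slices
    if (is.null(slice_mm)) slice_mm <- roi$slice_spacing_mm
  } else {
    n_slices <- as.integer(roi)
  }
  stopifnot(pitch_mm > 0, slice_mm > 0)
  pos <- (seq_len(n_rows) - 1) * pitch_mm
  slice0 <- pmin(floor(pos / slice_mm + 1e-9), n_slices - 1)
  keep <- slice0 >= 0 & pos <= n_slices * slice_mm + 1e-9
  map <- ifelse(keep, as.integer(slice0) + 1L, NA_integer_)
  structure(list(map = map,
                 table = data.frame(row = seq_len(n_rows) - 1L,
                                    position_mm = pos, slice = slice0),
                 pitch_mm = pitch_mm, slice_mm = slice_mm),
            class = "longitudinal_map")
}

#' Hue-brightness rendering of the optic-axis carpet
#'
#' Orientation maps to color hue over `[0, 180)` degrees with 0 degrees
#' (circumferential) rendered blue; local retardance, clipped to
#' `display_max`, maps to brightness; masked pixels are black; saturation
#' is fixed at 1.
#'
#' @param carpet A `carpet_view`.
#' @param display_max Retardance mapped to full brightness (deg / 100 um).
#' @return An RGB array `[rows, cols, 3]` in `[0, 1]`.
#' @export
render_oa_hsv <- function(carpet, display_max = 30) {
  stopifnot(inherits(carpet, "carpet_view"), display_max > 0)
  ori <- carpet$orientation_deg
  ret <- carpet$ret_deg100
  msk <- carpet$mask & is.finite(ori) & is.finite(ret)
  h <- (2 / 3 + (ori %% 180) / 180) %% 1
  v <- pmin(pmax(ret / display_max, 0), 1)
  h[!msk] <- 0; v[!msk] <- 0
  cols <- grDevices::hsv(h, 1, v)
  rgb <- grDevices::col2rgb(cols) / 255
  out <- array(0, c(nrow(ori), ncol(ori), 3))
  out[, , 1] <- matrix(rgb[1, ], nrow(ori), ncol(ori))
  out[, , 2] <- matrix(rgb[2, ], nrow(ori), ncol(ori))
  out[, , 3] <- matrix(rgb[3, ], nrow(ori), ncol(ori))
  out
}
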