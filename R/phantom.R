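# Synthetic brain-like birefringence phantom and matched T1-like MRI rendering.
#
# The phantom is a stack of slabs transverse to a vertical insertion
# trajectory: grey-matter cortex, birefringent subcortical white matter,
# deep grey matter containing a highly birefringent, lab-fixed fiber tract
# (an internal-capsule-like landmark). Fiber fields come in two flavours:
#   - "apparent": constant apparent orientation relative to the probe frame
#     (circumferential/helical rings around the trajectory), and
#   - "lab": a fixed laboratory-frame unit vector.

#' Default phantom layer table
#'
#' Slab boundaries are distances (mm) along the trajectory from the cortical
#' entry. Later rows override earlier ones, which is how the fiber tract is
#' inset into the deep grey-matter slab.
#'
#' @param length_mm Total phantom length along the trajectory (mm).
#' @return A data frame with one row per layer.
#' @export
default_phantom_layers <- function(length_mm = 25.08) {
  data.frame(
    name = c("cortex", "subcortical_wm", "deep_gm", "tract"),
    class = c(1L, 2L, 3L, 4L),
    z0_mm = c(0, 2, 10, 13),
    z1_mm = c(2, 10, length_mm, 15),
    dn = c(0, 2e-4, 0, 5e-4),
    fiber_mode = c("none", "apparent", "none", "lab"),
    theta_deg = c(NA, 0, NA, NA),
    fx = c(NA, NA, NA, 1),
    fy = c(NA, NA, NA, 0),
    fz = c(NA, NA, NA, 0),
    stringsAsFactors = FALSE
  )
}

#' Phantom configuration
#'
#' @param voxel_mm Phantom grid pitch (mm); the default 0.114 mm makes the
#'   default 0.57 mm MRI voxel an exact 5x5x5 block.
#' @param lateral_mm Lateral extent (mm) of the square cross-section.
#' @param length_mm Extent (mm) along the trajectory axis.
#' @param layers Layer table, see [default_phantom_layers()].
#' @param scattering Named or class-indexed reflectivity per tissue class.
#' @param mri_intensity Class-indexed T1-like intensity per tissue class.
#' @param birefringence_sign +1 or -1; brain white matter is negatively
#'   birefringent, so the default is -1 (reported fiber orientations are the
#'   measured retarder axes flipped by 90 degrees).
#' @param dn_noise_sd Relative jitter of the per-voxel birefringence on
#'   birefringent voxels (0 disables; seeded).
#' @return A list of class `phantom_config`.
#' @export
phantom_config <- function(voxel_mm = 0.114, lateral_mm = 6.27, length_mm = 25.08,
                           layers = default_phantom_layers(length_mm),
                           scattering = c(0.4, 1.0, 0.4, 1.0),
                           mri_intensity = c(0.55, 1.0, 0.55, 1.0),
                           birefringence_sign = -1,
                           dn_noise_sd = 0) {
  stopifnot(voxel_mm > 0, lateral_mm > 0, length_mm > 0,
            birefringence_sign %in% c(-1, 1), dn_noise_sd >= 0)
  validate_layers(layers, length_mm)
  structure(list(voxel_mm = voxel_mm, lateral_mm = lateral_mm,
                 length_mm = length_mm, layers = layers,
                 scattering = scattering, mri_intensity = mri_intensity,
                 birefringence_sign = birefringence_sign,
                 dn_noise_sd = dn_noise_sd),
            class = "phantom_config")
}

validate_layers <- function(layers, length_mm) {
  need <- c("name", "class", "z0_mm", "z1_mm", "dn", "fiber_mode")
  if (!all(need %in% names(layers))) {
    stop("layer table must have columns: ", paste(need, collapse = ", "))
  }
  if (any(layers$z1_mm <= layers$z0_mm)) stop("layer with z1 <= z0")
  if (any(layers$z0_mm < 0) || any(layers$z1_mm > length_mm + 1e-9)) {
    stop("layer boundaries out of the phantom range [0, ", length_mm, "] mm")
  }
  if (any(layers$dn < 0)) stop("negative birefringence magnitude in layer table")
  # every depth must be covered by at least one layer
  zc <- seq(1e-6, length_mm - 1e-6, length.out = 512)
  hit <- vapply(zc, function(z) any(z >= layers$z0_mm & z < layers$z1_mm), logical(1))
  if (!all(hit)) stop("layer table leaves uncovered gaps along the trajectory")
  invisible(TRUE)
}

# last matching layer wins (overrides)
layer_at_z <- function(config, z_mm) {
  hits <- which(z_mm >= config$layers$z0_mm & z_mm < config$layers$z1_mm)
  if (length(hits) == 0) {
    if (abs(z_mm - config$length_mm) < 1e-9) hits <- nrow(config$layers) else
      stop("position ", z_mm, " mm outside the phantom")
  }
  config$layers[hits[length(hits)], ]
}

#' Build the layered birefringence phantom
#'
#' Materializes the label, birefringence and fiber-direction grids of the
#' configured slab stack. Deterministic for a given seed (the seed only
#' matters when `dn_noise_sd > 0`).
#'
#' @param config A [phantom_config()].
#' @param seed Integer seed recorded in the phantom.
#' @return A list of class `tissue_phantom` with `labels` (integer array),
#'   `dn` (array), `fiber` (array `[nx, ny, nz, 3]`, unit vectors where
#'   `dn > 0`), `voxel_um`, `sign`, `axis_xy_mm`, and the `config`.
#' @export
build_dbs_phantom <- function(config = phantom_config(), seed = 1L) {
  stopifnot(inherits(config, "phantom_config"))
  nx <- ny <- round(config$lateral_mm / config$voxel_mm)
  nz <- round(config$length_mm / config$voxel_mm)
  axis_xy <- rep(config$lateral_mm / 2, 2)
  zc <- (seq_len(nz) - 0.5) * config$voxel_mm
  lab <- integer(nz); dnv <- numeric(nz)
  mode <- character(nz); th <- numeric(nz); fvec <- matrix(0, nz, 3)
  for (k in seq_len(nz)) {
    L <- layer_at_z(config, zc[k])
    lab[k] <- L$class; dnv[k] <- L$dn; mode[k] <- L$fiber_mode
    th[k] <- ifelse(is.na(L$theta_deg), 0, L$theta_deg)
    fvec[k, ] <- c(L$fx, L$fy, L$fz)
  }
  labels <- array(rep(lab, each = nx * ny), dim = c(nx, ny, nz))
  dn <- array(rep(dnv, each = nx * ny), dim = c(nx, ny, nz))
  if (config$dn_noise_sd > 0) {
    set.seed(as.integer(seed))
    jit <- array(stats::rnorm(length(dn), 1, config$dn_noise_sd), dim = dim(dn))
    dn <- dn * ifelse(dn > 0, pmax(0, jit), 1)
  }
  # fiber field
  xc <- (seq_len(nx) - 0.5) * config$voxel_mm - axis_xy[1]
  yc <- (seq_len(ny) - 0.5) * config$voxel_mm - axis_xy[2]
  phi <- atan2(rep(yc, each = nx), rep(xc, times = ny))  # [nx*ny]
  fiber <- array(0, dim = c(nx, ny, nz, 3))
  for (k in seq_len(nz)) {
    if (dnv[k] <= 0 || mode[k] == "none") next
    if (mode[k] == "apparent") {
      a <- th[k] * pi / 180
      # fiber = cos(theta) * tangential + sin(theta) * axial
      tx <- -sin(phi); ty <- cos(phi)
      fiber[, , k, 1] <- cos(a) * tx
      fiber[, , k, 2] <- cos(a) * ty
      fiber[, , k, 3] <- sin(a)
    } else {
      f <- fvec[k, ] / sqrt(sum(fvec[k, ]^2))
      fiber[, , k, 1] <- f[1]; fiber[, , k, 2] <- f[2]; fiber[, , k, 3] <- f[3]
    }
  }
  structure(list(labels = labels, dn = dn, fiber = fiber,
                 voxel_um = config$voxel_mm * 1000,
                 sign = config$birefringence_sign,
                 axis_xy_mm = axis_xy, seed = as.integer(seed),
                 config = config),
            class = "tissue_phantom")
}

#' Insertion trajectory
#'
#' @param entry_mm Entry point at the cortical surface, phantom coordinates (mm).
#' @param direction Unit direction; restricted to the +z grid axis.
#' @param length_mm Pullback length in mm (default 23).
#' @return A list of class `trajectory`.
#' @export
trajectory <- function(entry_mm = c(3.135, 3.135, 0), direction = c(0, 0, 1),
                       length_mm = 23) {
  stopifnot(length(entry_mm) == 3, length(direction) == 3, length_mm > 0)
  direction <- direction / sqrt(sum(direction^2))
  if (max(abs(direction - c(0, 0, 1))) > 1e-9) {
    stop("only trajectories along the +z grid axis are supported")
  }
  structure(list(entry_mm = entry_mm, direction = direction, length_mm = length_mm),
            class = "trajectory")
}

check_trajectory_inside <- function(phantom, traj) {
  cfg <- phantom$config
  if (traj$entry_mm[3] < -1e-9 ||
      traj$entry_mm[3] + traj$length_mm > cfg$length_mm + 1e-9) {
    stop("trajectory exits the phantom along z")
  }
  if (any(traj$entry_mm[1:2] < 0) || any(traj$entry_mm[1:2] > cfg$lateral_mm)) {
    stop("trajectory entry outside the phantom cross-section")
  }
  invisible(TRUE)
}

#' MRI-like rendering of the phantom
#'
#' Each MRI voxel value is the volume-weighted average of the class
#' intensities over the phantom voxels it covers (exact fractional 1-D
#' overlap weights per axis), plus seeded Gaussian noise. This reproduces
#' the partial-volume mixing of a coarse T1-weighted acquisition.
#'
#' @param phantom A `tissue_phantom`.
#' @param voxel_mm MRI voxel size in mm (scalar isotropic or 3-vector);
#'   default 0.57 isotropic.
#' @param intensity_map Class-indexed intensities; defaults to the phantom
#'   config's T1-like map (white matter bright).
#' @param noise_sd Gaussian noise standard deviation (image units).
#' @param seed Integer seed for the noise.
#' @return A list of class `mri_volume` with `data`, `voxel_mm`, `origin_mm`,
#'   and a `coverage` array (covered phantom volume per voxel, mm^3).
#' @export
render_mri <- function(phantom, voxel_mm = 0.57, intensity_map = NULL,
                       noise_sd = 0.02, seed = 1L) {
  stopifnot(inherits(phantom, "tissue_phantom"), all(voxel_mm > 0), noise_sd >= 0)
  if (length(voxel_mm) == 1) voxel_mm <- rep(voxel_mm, 3)
  if (is.null(intensity_map)) intensity_map <- phantom$config$mri_intensity
  img <- array(intensity_map[phantom$labels], dim = dim(phantom$labels))
  pv <- phantom$voxel_um / 1000
  ext <- dim(img) * pv
  ndim <- ceiling(ext / voxel_mm - 1e-9)
  W <- lapply(1:3, function(ax) overlap_weights(ndim[ax], voxel_mm[ax], dim(img)[ax], pv))
  vol <- contract_axis(contract_axis(contract_axis(img, W[[1]]$frac, 1), W[[2]]$frac, 2),
                       W[[3]]$frac, 3)
  cov1 <- lapply(1:3, function(ax) rowSums(W[[ax]]$len))
  covered <- outer(outer(cov1[[1]], cov1[[2]]), cov1[[3]])
  if (noise_sd > 0) {
    set.seed(as.integer(seed))
    vol <- vol + array(stats::rnorm(length(vol), 0, noise_sd), dim = dim(vol))
  }
  structure(list(data = vol, voxel_mm = voxel_mm, origin_mm = c(0, 0, 0),
                 coverage = covered),
            class = "mri_volume")
}

# 1-D overlap of MRI bins [i*dv, (i+1)*dv) with phantom cells [k*pv, (k+1)*pv).
# Returns absolute overlap lengths and row-normalized fractions.
overlap_weights <- function(n_mri, dv, n_ph, pv) {
  len <- matrix(0, n_mri, n_ph)
  for (i in seq_len(n_mri)) {
    a <- (i - 1) * dv; b <- i * dv
    k0 <- max(1L, floor(a / pv) + 1L)
    k1 <- min(n_ph, ceiling(b / pv - 1e-12))
    if (k1 < k0) next
    for (k in k0:k1) {
      len[i, k] <- max(0, min(b, k * pv) - max(a, (k - 1) * pv))
    }
  }
  frac <- len / pmax(rowSums(len), .Machine$double.eps)
  list(len = len, frac = frac)
}

# apply weight matrix W [nout, nin] along axis `ax` of a 3-D array
contract_axis <- function(arr, W, ax) {
  d <- dim(arr)
  perm <- c(ax, setdiff(1:3, ax))
  m <- matrix(aperm(arr, perm), nrow = d[ax])
  out <- W %*% m
  res <- array(out, dim = c(nrow(W), d[setdiff(1:3, ax)]))
  aperm(res, order(perm))
}

#' Ground-truth carpet maps along a planned pullback
#'
#' For every (frame, A-line pair) of the planned helical pullback, returns
#' the true local retardance (deg per 100 um, double-pass) and the true
#' apparent fiber orientation at the carpet sampling depth, from the phantom
#' layer stack and the beam-projection geometry.
#'
#' @param phantom A `tissue_phantom`.
#' @param traj A [trajectory()] inside the phantom.
#' @param acq An [acq_config()].
#' @return A list of class `truth_carpet` with matrices `[frame, pair]`:
#'   `ret_deg100`, `orientation_deg` (fiber orientation, NA where undefined),
#'   `defined`, plus `pair_azimuth_deg`, `z_mm`, and geometry metadata.
#' @export
true_maps_along_trajectory <- function(phantom, traj, acq) {
  check_trajectory_inside(phantom, traj)
  geo <- pullback_geometry(acq, traj$length_mm)
  nframes <- geo$frames
  npair <- acq$alines_per_frame / 2
  dalpha <- 360 / acq$alines_per_frame
  pair_az <- (acq$start_azimuth_deg + (2 * seq_len(npair) - 1.5) * dalpha) %% 360
  z <- traj$entry_mm[3] + (seq_len(nframes) - 0.5) * geo$pitch_mm
  ret <- matrix(0, nframes, npair)
  ori <- matrix(NA_real_, nframes, npair)
  def <- matrix(FALSE, nframes, npair)
  for (f in seq_len(nframes)) {
    L <- layer_at_z(phantom$config, z[f])
    if (L$dn <= 0 || L$fiber_mode == "none") next
    if (L$fiber_mode == "apparent") {
      ret[f, ] <- ret_deg100_from_dn(L$dn, 1, acq)
      ori[f, ] <- L$theta_deg %% 180
      def[f, ] <- TRUE
    } else {
      fv <- c(L$fx, L$fy, L$fz)
      pr <- project_fiber_orientation(fv / sqrt(sum(fv^2)), pair_az)
      ret[f, ] <- ret_deg100_from_dn(L$dn, pr$scale, acq)
      ori[f, ] <- pr$orientation_deg
      def[f, ] <- pr$defined
    }
  }
  ori <- ori %% 180
  structure(list(ret_deg100 = ret, orientation_deg = ori, defined = def,
                 pair_azimuth_deg = pair_az, z_mm = z, pitch_mm = geo$pitch_mm,
                 sign = phantom$sign),
            class = "truth_carpet")
}

# double-pass local retardance in degrees per 100 um from a birefringence
# magnitude and the beam-projection scaling |f_perp|^2
ret_deg100_from_dn <- function(dn, scale, acq) {
  lam_um <- acq$center_wavelength_nm / 1000
  (2 * pi * dn * scale * (2 * 100) / lam_um) * 180 / pi
}
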