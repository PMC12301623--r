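# Forward model of the rotating-catheter PS-OCT acquisition.

#' Acquisition configuration
#'
#' System and scan-geometry parameters of the swept-source, catheter-based
#' PS-OCT acquisition, plus the noise model of the simulator.
#'
#' @param center_wavelength_nm Source center wavelength (default 1300 nm).
#' @param sweep_range_nm Wavelength scanning range (default 110 nm).
#' @param aline_rate_hz A-line repetition rate (default 50 kHz).
#' @param alines_per_frame A-lines per catheter rotation; the full system
#'   value is 2048, the default here is a reduced 512 for desk-scale runs.
#'   Must be even and >= 8.
#' @param frames_per_second Catheter rotations per second (default 25).
#' @param pullback_speed_mm_s Pullback speed (default 5 mm/s).
#' @param axial_pixel_um Axial pixel size in tissue (default 4.8 um).
#' @param imaging_depth_mm Reconstructed tissue depth beyond the sheath
#'   (default 1.5 mm).
#' @param lateral_resolution_um Lateral spot size (default 40 um).
#' @param spectral_bins Number of spectral bins (default 1).
#' @param spectral_system_deg Magnitude of the static, bin-dependent system
#'   rotation swept linearly across bins (default 0 = identity).
#' @param start_azimuth_deg Azimuth of the first A-line of every frame.
#' @param speckle Logical, multiplicative circular complex speckle shared by
#'   both detection channels and both states of an A-line pair.
#' @param detector_noise_sd Additive complex detector noise standard
#'   deviation per channel (field units; the white-matter field amplitude at
#'   the sheath exit is ~1).
#' @param attenuation_mm Amplitude attenuation rate in tissue (1/mm).
#' @param pre_sheath_px Depth pixels recorded before the sheath inner surface.
#' @return A list of class `acq_config`.
#' @export
acq_config <- function(center_wavelength_nm = 1300, sweep_range_nm = 110,
                       aline_rate_hz = 50e3, alines_per_frame = 512,
                       frames_per_second = 25, pullback_speed_mm_s = 5,
                       axial_pixel_um = 4.8, imaging_depth_mm = 1.5,
                       lateral_resolution_um = 40, spectral_bins = 1,
                       spectral_system_deg = 0, start_azimuth_deg = 0,
                       speckle = TRUE, detector_noise_sd = 0.1,
                       attenuation_mm = 0.5, pre_sheath_px = 2) {
  stopifnot(center_wavelength_nm > 0, alines_per_frame >= 8,
            alines_per_frame %% 2 == 0, frames_per_second > 0,
            pullback_speed_mm_s > 0, axial_pixel_um > 0, imaging_depth_mm > 0,
            spectral_bins >= 1, detector_noise_sd >= 0, attenuation_mm >= 0,
            pre_sheath_px >= 0)
  structure(list(center_wavelength_nm = center_wavelength_nm,
                 sweep_range_nm = sweep_range_nm, aline_rate_hz = aline_rate_hz,
                 alines_per_frame = as.integer(alines_per_frame),
                 frames_per_second = frames_per_second,
                 pullback_speed_mm_s = pullback_speed_mm_s,
                 axial_pixel_um = axial_pixel_um,
                 imaging_depth_mm = imaging_depth_mm,
                 lateral_resolution_um = lateral_resolution_um,
                 spectral_bins = as.integer(spectral_bins),
                 spectral_system_deg = spectral_system_deg,
                 start_azimuth_deg = start_azimuth_deg,
                 speckle = speckle, detector_noise_sd = detector_noise_sd,
                 attenuation_mm = attenuation_mm,
                 pre_sheath_px = as.integer(pre_sheath_px)),
            class = "acq_config")
}

#' Helical pullback geometry arithmetic
#'
#' Frame count, pitch, rotation rate and angular sampling implied by an
#' acquisition configuration and a pullback length.
#'
#' @param acq An [acq_config()].
#' @param pullback_length_mm Pullback length in mm (default 23).
#' @return A list with `pitch_mm`, `frames`, `rpm`, `deg_per_aline`,
#'   `duration_s`.
#' @export
pullback_geometry <- function(acq, pullback_length_mm = 23) {
  pitch <- acq$pullback_speed_mm_s / acq$frames_per_second
  stopifnot(pitch > 0)
  frames <- round(pullback_length_mm / pitch)
  list(pitch_mm = pitch, frames = as.integer(frames),
       rpm = acq$frames_per_second * 60,
       deg_per_aline = 360 / acq$alines_per_frame,
       duration_s = frames / acq$frames_per_second)
}

#' Catheter model
#'
#' Geometry and polarization properties of the rotating catheter: the
#' birefringent protective sheath (the guide star) and the per-A-line
#' transmission offsets introduced by catheter rotation, modelled as
#' rotations about the circular Poincare axis parameterized by a smooth
#' periodic orientation offset plus a slow drift.
#'
#' @param sheath_od_mm Sheath outer diameter (default 2.3 mm).
#' @param sheath_thickness_um Sheath wall thickness (default 200 um).
#' @param sheath_retardance Total sheath retardance across the wall,
#'   radians (default 0.3); must be > 0 for the guide star to be visible.
#' @param sheath_orientation_deg Sheath optic-axis orientation in the probe
#'   frame (default 0 = circumferential).
#' @param sheath_reflectivity Backscatter amplitude of the sheath material.
#' @param offset_constant_deg Constant orientation offset applied to every
#'   A-line (degrees).
#' @param offset_amplitude_deg Amplitude of the periodic per-A-line
#'   orientation offset (degrees).
#' @param offset_harmonic Azimuthal harmonic of the periodic offset.
#' @param offset_phase_deg Phase of the periodic offset.
#' @param drift_deg_total Slow orientation drift accumulated over the full
#'   pullback (degrees).
#' @return A list of class `catheter_model`.
#' @export
catheter_model <- function(sheath_od_mm = 2.3, sheath_thickness_um = 200,
                           sheath_retardance = 0.3, sheath_orientation_deg = 0,
                           sheath_reflectivity = 0.7,
                           offset_constant_deg = 0,
                           offset_amplitude_deg = 20, offset_harmonic = 1,
                           offset_phase_deg = 0, drift_deg_total = 10) {
  stopifnot(sheath_od_mm > 0, sheath_thickness_um > 0, sheath_retardance >= 0,
            sheath_reflectivity >= 0, offset_harmonic >= 1)
  if (sheath_retardance == 0) {
    warning("zero sheath retardance: the guide star is disabled")
  }
  structure(list(sheath_od_mm = sheath_od_mm,
                 sheath_thickness_um = sheath_thickness_um,
                 sheath_retardance = sheath_retardance,
                 sheath_orientation_deg = sheath_orientation_deg,
                 sheath_reflectivity = sheath_reflectivity,
                 offset_constant_deg = offset_constant_deg,
                 offset_amplitude_deg = offset_amplitude_deg,
                 offset_harmonic = offset_harmonic,
                 offset_phase_deg = offset_phase_deg,
                 drift_deg_total = drift_deg_total),
            class = "catheter_model")
}

#' Per-A-line transmission orientation offset
#'
#' The optic-axis orientation offset (degrees) introduced by the catheter
#' transmission at azimuth `azimuth_deg` and pullback fraction `frame_frac`.
#'
#' @param cath A [catheter_model()].
#' @param azimuth_deg Catheter azimuth(s), degrees.
#' @param frame_frac Fraction of the pullback completed, in `[0, 1]`.
#' @return Offset(s) in degrees.
#' @export
transmission_offset_deg <- function(cath, azimuth_deg, frame_frac = 0) {
  a <- (azimuth_deg + cath$offset_phase_deg) * pi / 180
  cath$offset_constant_deg +
    cath$offset_amplitude_deg * sin(cath$offset_harmonic * a) +
    cath$drift_deg_total * frame_frac
}

#' Static per-bin system rotation
#'
#' Wavelength-dependent polarization effects of static system components,
#' modelled as an extra rotation about the circular axis whose equivalent
#' orientation offset sweeps linearly from `-spectral_system_deg` to
#' `+spectral_system_deg` across the spectral bins (an orientation offset of
#' `phi` degrees is the Poincare rotation by `-2 phi`). With one bin (or
#' zero magnitude) this is the identity.
#'
#' @param acq An [acq_config()].
#' @param bin Bin index in `1:spectral_bins`.
#' @return A 3x3 rotation matrix, composed into the transmission of fields
#'   attributed to that bin.
#' @export
spectral_system_model <- function(acq, bin) {
  stopifnot(bin >= 1, bin <= acq$spectral_bins)
  ang <- spectral_bin_angles_deg(acq)[bin]
  if (ang == 0) return(diag(3))
  rot_axis_angle(c(0, 0, 1), -2 * ang * pi / 180)
}

spectral_bin_angles_deg <- function(acq) {
  B <- acq$spectral_bins
  if (B == 1 || acq$spectral_system_deg == 0) return(rep(0, B))
  acq$spectral_system_deg * (2 * (seq_len(B) - 1) / (B - 1) - 1)
}

#' Apparent fiber orientation seen by a radial beam
#'
#' Projects a unit fiber direction onto the plane perpendicular to the
#' imaging beam at catheter azimuth `alpha`. The beam is
#' `b = (cos a, sin a, 0)`; the in-plane frame is the circumferential
#' tangent `t = z x b` (orientation 0 deg) and the trajectory axis `z`
#' (90 deg). Fibers parallel to the beam produce no measurable
#' birefringence: the effective retardance scaling is `|f_perp|^2`.
#'
#' @param fiber Unit 3-vector (laboratory frame).
#' @param azimuth_deg Beam azimuth(s), degrees; vectorized.
#' @param tol Projections with `|f_perp| < tol` are undefined.
#' @return A list with `orientation_deg` in `[0, 180)` (NA where undefined),
#'   `scale` (`|f_perp|^2`), and `defined`.
#' @export
project_fiber_orientation <- function(fiber, azimuth_deg, tol = 1e-6) {
  if (abs(sqrt(sum(fiber^2)) - 1) > 1e-6) stop("fiber direction must be a unit vector")
  a <- azimuth_deg * pi / 180
  bx <- cos(a); by <- sin(a)
  fb <- fiber[1] * bx + fiber[2] * by
  px <- fiber[1] - fb * bx
  py <- fiber[2] - fb * by
  pz <- fiber[3]
  # components in the (t, z) image plane; t = (-sin a, cos a, 0)
  ct <- -px * sin(a) + py * cos(a)
  cz <- pz
  norm2 <- px^2 + py^2 + pz^2
  defined <- sqrt(norm2) >= tol
  ori <- (atan2(cz, ct) * 180 / pi) %% 180
  ori[!defined] <- NA_real_
  list(orientation_deg = ori, scale = norm2, defined = defined)
}

#' Simulate a helical PS-OCT pullback
#'
#' Forward model: for each A-line the radial layer stack is built (sheath
#' retarder first, then tissue layers one axial pixel thick), the one-way
#' product `P(z)` and round trip `C(z) = P(z) dT(P(z))` are formed, the
#' catheter/system transmission is applied as
#' `R_meas(z) = dT(T(alpha)) C(z) T(alpha)`, each rotation is lifted to a
#' 2x2 field operator (half-angle lift, global phase fixed to zero), and the
#' detected fields are the operator applied to the alternating input states,
#' scaled by class-dependent scattering, exponential attenuation and shared
#' circular complex speckle, plus additive detector noise. Subsequent
#' A-lines alternate the two input polarization states (orthogonal on the
#' Poincare sphere).
#'
#' @param phantom A `tissue_phantom`.
#' @param traj A [trajectory()].
#' @param cath A [catheter_model()].
#' @param acq An [acq_config()].
#' @param seed Integer seed for speckle and detector noise.
#' @return A list of class `pullback_raw` with complex field arrays `Eh`,
#'   `Ev` of dim `[depth, A-line, frame, bin]`, per-A-line metadata, the
#'   sheath depth band, configuration objects and stored ground truth.
#' @export
simulate_pullback <- function(phantom, traj, cath = catheter_model(),
                              acq = acq_config(), seed = 1L) {
  check_trajectory_inside(phantom, traj)
  geo <- pullback_geometry(acq, traj$length_mm)
  nA <- acq$alines_per_frame
  nframes <- geo$frames
  n_sheath <- round(cath$sheath_thickness_um / acq$axial_pixel_um)
  n_tissue <- round(acq$imaging_depth_mm * 1000 / acq$axial_pixel_um)
  if (n_sheath < 1) stop("sheath thinner than one axial pixel")
  n_pre <- acq$pre_sheath_px
  nz <- n_pre + n_sheath + n_tissue
  sheath_band <- n_pre + seq_len(n_sheath)
  tissue0 <- n_pre + n_sheath  # last non-tissue index

  lam_um <- acq$center_wavelength_nm / 1000
  pix_um <- acq$axial_pixel_um
  flip <- if (phantom$sign < 0) 90 else 0

  alpha <- (acq$start_azimuth_deg + (seq_len(nA) - 1) * 360 / nA) %% 360
  state_b <- (seq_len(nA) %% 2) == 0  # even A-lines probe input state 2

  # per-A-line layer stacks (depth x A-line), shared structure across frames
  ret <- matrix(0, nz, nA)
  az2 <- matrix(0, nz, nA)
  amp <- matrix(0.0, nz, nA)
  if (n_pre > 0) amp[seq_len(n_pre), ] <- 0.05  # faint pre-sheath return
  s_az2 <- 2 * cath$sheath_orientation_deg * pi / 180
  ret[sheath_band, ] <- cath$sheath_retardance / n_sheath
  az2[sheath_band, ] <- s_az2
  amp[sheath_band, ] <- sqrt(cath$sheath_reflectivity)
  tz <- seq_len(n_tissue)
  atten <- exp(-acq$attenuation_mm * tz * pix_um / 1000)

  npair <- nA / 2
  bins <- acq$spectral_bins
  bin_angles <- spectral_bin_angles_deg(acq)
  Eh <- array(0i, dim = c(nz, nA, nframes, bins))
  Ev <- array(0i, dim = c(nz, nA, nframes, bins))
  offsets <- matrix(0, npair, nframes)

  set.seed(as.integer(seed))
  z_mm <- traj$entry_mm[3] + (seq_len(nframes) - 0.5) * geo$pitch_mm
  scat <- phantom$config$scattering

  for (f in seq_len(nframes)) {
    L <- layer_at_z(phantom$config, z_mm[f])
    if (L$dn > 0 && L$fiber_mode != "none") {
      if (L$fiber_mode == "apparent") {
        theta <- rep(L$theta_deg, nA)
        scale <- rep(1, nA)
        defined <- rep(TRUE, nA)
      } else {
        fv <- c(L$fx, L$fy, L$fz)
        pr <- project_fiber_orientation(fv / sqrt(sum(fv^2)), alpha)
        theta <- pr$orientation_deg
        scale <- pr$scale
        defined <- pr$defined
        theta[!defined] <- 0
      }
      dvec <- 2 * pi * L$dn * scale * (2 * pix_um) / lam_um
      ret[tissue0 + tz, ] <- matrix(dvec, n_tissue, nA, byrow = TRUE)
      az2[tissue0 + tz, ] <- matrix(2 * (theta + flip) * pi / 180, n_tissue, nA,
                                    byrow = TRUE)
    } else {
      ret[tissue0 + tz, ] <- 0
      az2[tissue0 + tz, ] <- 0
    }
    amp[tissue0 + tz, ] <- sqrt(scat[L$class]) * atten

    frac <- (f - 0.5) / nframes
    off_deg <- transmission_offset_deg(cath, alpha, frac)
    offsets[, f] <- (off_deg[seq(1, nA, by = 2)] + off_deg[seq(2, nA, by = 2)]) / 2
    psi0 <- -2 * off_deg * pi / 180

    if (acq$speckle) {
      gp <- matrix(stats::rnorm(nz * npair, 0, 1 / sqrt(2)), nz, npair)
      gq <- matrix(stats::rnorm(nz * npair, 0, 1 / sqrt(2)), nz, npair)
      gre <- gp[, rep(seq_len(npair), each = 2)]
      gim <- gq[, rep(seq_len(npair), each = 2)]
    } else {
      gre <- matrix(1, nz, nA); gim <- matrix(0, nz, nA)
    }
    sdn <- acq$detector_noise_sd / sqrt(2)
    mknoise <- function() {
      if (sdn > 0) matrix(stats::rnorm(nz * nA, 0, sdn), nz, nA) else matrix(0, nz, nA)
    }
    nhre <- mknoise(); nhim <- mknoise(); nvre <- mknoise(); nvim <- mknoise()

    for (b in seq_len(bins)) {
      psi <- psi0 + (-2 * bin_angles[b] * pi / 180)
      fl <- cpp_simulate_fields(ret, az2, psi, amp, gre, gim,
                                nhre, nhim, nvre, nvim, state_b)
      Eh[, , f, b] <- fl$Eh
      Ev[, , f, b] <- fl$Ev
    }
  }

  truth <- true_maps_along_trajectory(phantom, traj, acq)
  structure(list(Eh = Eh, Ev = Ev,
                 azimuth_deg = alpha, state_b = state_b,
                 sheath_band = sheath_band, n_pre = n_pre,
                 n_sheath = n_sheath, n_tissue = n_tissue,
                 pitch_mm = geo$pitch_mm, frames = nframes,
                 acq = acq, catheter = cath, phantom_sign = phantom$sign,
                 truth = truth, truth_offset_deg = offsets,
                 seed = as.integer(seed)),
            class = "pullback_raw")
}
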