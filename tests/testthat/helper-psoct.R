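# Shared fixtures: tiny phantoms and cached small simulations.

# homogeneous white-matter slab with constant apparent orientation
slab_phantom <- function(theta_deg = 30, dn = 2e-4, length_mm = 6,
                         sign = -1) {
  layers <- data.frame(name = "wm", class = 2L, z0_mm = 0, z1_mm = length_mm,
                       dn = dn, fiber_mode = "apparent", theta_deg = theta_deg,
                       fx = NA, fy = NA, fz = NA)
  build_dbs_phantom(phantom_config(length_mm = length_mm, lateral_mm = 6.27,
                                   layers = layers, birefringence_sign = sign),
                    seed = 1)
}

# lab-fixed horizontal fiber tract filling the whole phantom
tract_phantom <- function(dn = 5e-4, length_mm = 6) {
  layers <- data.frame(name = "tract", class = 4L, z0_mm = 0, z1_mm = length_mm,
                       dn = dn, fiber_mode = "lab", theta_deg = NA,
                       fx = 1, fy = 0, fz = 0)
  build_dbs_phantom(phantom_config(length_mm = length_mm, lateral_mm = 6.27,
                                   layers = layers), seed = 1)
}

# grey matter only (no birefringent tissue)
gm_phantom <- function(length_mm = 6) {
  layers <- data.frame(name = "gm", class = 1L, z0_mm = 0, z1_mm = length_mm,
                       dn = 0, fiber_mode = "none", theta_deg = NA,
                       fx = NA, fy = NA, fz = NA)
  build_dbs_phantom(phantom_config(length_mm = length_mm, lateral_mm = 6.27,
                                   layers = layers), seed = 1)
}

tiny_acq <- function(...) {
  do.call(acq_config, utils::modifyList(
    list(alines_per_frame = 64, imaging_depth_mm = 0.4,
         speckle = FALSE, detector_noise_sd = 0), list(...)))
}

quiet_cath <- function(...) {
  do.call(catheter_model, utils::modifyList(
    list(offset_constant_deg = 0, offset_amplitude_deg = 0,
         drift_deg_total = 0), list(...)))
}

noise_free_opts <- function(...) {
  do.call(recon_options, utils::modifyList(
    list(filter_axial_sigma = 0, filter_lateral_sigma = 0,
         local_axial_sigma = 0, local_lateral_sigma = 0,
         offset_smooth_window = 3), list(...)))
}

# tissue depth indices of a pullback
tissue_depths <- function(raw) {
  raw$n_pre + raw$n_sheath + seq_len(raw$n_tissue)
}

# absolute circular orientation error (degrees, period 180)
orient_err <- function(est, truth) {
  abs(((est - truth + 90) %% 180) - 90)
}

# one cached noise-free slab pullback + reconstruction, reused across tests
slab_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ph <- slab_phantom()
      traj <- trajectory(length_mm = 2)
      raw <- simulate_pullback(ph, traj, quiet_cath(), tiny_acq(), seed = 11)
      lb <- reconstruct_pullback(raw, noise_free_opts())
      cache <<- list(phantom = ph, raw = raw, lb = lb)
    }
    cache
  }
})

# random rotation matrix (uniform axis, uniform angle)
random_rotation <- function() {
  ax <- stats::rnorm(3)
  rot_axis_angle(ax / sqrt(sum(ax^2)), stats::runif(1, 0, pi))
}
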