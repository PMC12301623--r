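# Stokes filtering, cumulative retrieval, compensation, peeling, guide star.

test_that("zero filter width leaves the Stokes volume unfiltered", {
  fx <- slab_fixture()
  raw <- fx$raw
  sv <- compute_stokes(raw, noise_free_opts())
  i1 <- seq(1, dim(raw$Eh)[2], by = 2)
  st <- stokes_from_fields(raw$Eh[, i1, , 1], raw$Ev[, i1, , 1])
  expect_equal(sv$S1[, , , 1], array(st$q, dim(st$q)), tolerance = 1e-12)
  expect_equal(sv$S1[, , , 3], array(st$v, dim(st$v)), tolerance = 1e-12)
  expect_equal(sv$I1, array(st$intensity, dim(st$q)), tolerance = 1e-12)
})

test_that("Gaussian filtering reduces state noise monotonically in width", {
  ph <- slab_phantom()
  traj <- trajectory(length_mm = 1)
  acq <- acq_config(alines_per_frame = 64, imaging_depth_mm = 0.25,
                    speckle = TRUE, detector_noise_sd = 0.1)
  # truth: cumulative rotation applied to input state 1, per depth
  cath <- quiet_cath()
  errs <- matrix(NA_real_, 10, 3)
  for (s in 1:10) {
    raw <- simulate_pullback(ph, traj, cath, acq, seed = 100 + s)
    tz <- tissue_depths(raw)
    n_sheath <- raw$n_sheath
    true_s1 <- sapply(seq_along(tz), function(i) {
      th <- c(rep(raw$catheter$sheath_orientation_deg, n_sheath),
              rep((30 + 90) %% 180, i))  # retarder axes incl. negative-sign flip
      dd <- c(rep(raw$catheter$sheath_retardance / n_sheath, n_sheath),
              rep(2 * pi * 2e-4 * (2 * acq$axial_pixel_um) /
                    (acq$center_wavelength_nm / 1000), i))
      P <- diag(3)
      for (k in seq_along(th)) P <- P %*% linear_retarder(th[k], dd[k])
      (P %*% d_transpose(P)) %*% c(1, 0, 0)
    })
    for (w in 1:3) {
      sig <- c(0, 2, 4)[w]
      sv <- compute_stokes(raw, recon_options(filter_axial_sigma = min(sig, 2),
                                              filter_lateral_sigma = sig))
      est <- sv$S1[tz, , , , drop = FALSE]
      d3 <- dim(est)[1:3]
      dot <- array(0, d3)
      for (k in 1:3) {
        dot <- dot + array(est[, , , k], d3) * array(true_s1[k, ], d3)
      }
      errs[s, w] <- mean(acos(pmax(-1, pmin(1, dot))))
    }
  }
  m <- colMeans(errs)
  expect_true(m[1] > m[2] && m[2] > m[3])
})

test_that("the cumulative map matches the simulator's round-trip rotation", {
  fx <- slab_fixture()
  raw <- fx$raw
  cm <- estimate_cumulative(compute_stokes(raw, noise_free_opts()),
                            noise_free_opts())
  acq <- raw$acq
  n_sheath <- raw$n_sheath
  dpx <- 2 * pi * 2e-4 * (2 * acq$axial_pixel_um) / (acq$center_wavelength_nm / 1000)
  # retarder orientation is the fiber orientation + 90 (negative birefringence)
  build_C <- function(n_tissue_px) {
    P <- diag(3)
    for (k in seq_len(n_sheath)) {
      P <- P %*% linear_retarder(0, raw$catheter$sheath_retardance / n_sheath)
    }
    for (k in seq_len(n_tissue_px)) P <- P %*% linear_retarder(120, dpx)
    P %*% d_transpose(P)
  }
  tz <- tissue_depths(raw)
  for (i in c(1, 40, length(tz))) {
    dev <- rotation_to_retvec(cm$C[, , tz[i], 5, 2] %*% t(build_C(i)))$angle
    expect_lt(dev, 1e-6)
  }
  expect_true(all(cm$valid[tz, , ]))

  # with transmission on, the measured map is dT(T) C T
  cath <- quiet_cath(offset_constant_deg = 25)
  raw_t <- simulate_pullback(fx$phantom, trajectory(length_mm = 1), cath,
                             tiny_acq(), seed = 12)
  cm_t <- estimate_cumulative(compute_stokes(raw_t, noise_free_opts()),
                              noise_free_opts())
  Tm <- rot_axis_angle(c(0, 0, 1), -2 * 25 * pi / 180)
  z <- tissue_depths(raw_t)[30]
  C_exp <- d_transpose(Tm) %*% build_C(30) %*% Tm
  dev <- rotation_to_retvec(cm_t$C[, , z, 5, 1] %*% t(C_exp))$angle
  expect_lt(dev, 1e-6)
})

test_that("compensation is a near-identity on clean symmetric data", {
  fx <- slab_fixture()
  raw <- fx$raw
  cm <- estimate_cumulative(compute_stokes(raw, noise_free_opts()),
                            noise_free_opts())
  cc <- compensate_transmission(cm, noise_free_opts(comp_window_pairs = 3,
                                                    comp_window_frames = 1))
  expect_lt(max(abs(cc$C - cm$C)), 1e-6)
  expect_lt(max(sqrt(colSums(matrix(cc$vhat, 3)^2))), 1e-3)
  expect_lt(max(cc$residual_asymmetry), 1e-8)
})

test_that("compensation preserves rotation angles and restores symmetry", {
  ph <- slab_phantom()
  # offsets constant within a frame (drift along the pullback) so that both
  # states of a pair share one transmission
  cath <- quiet_cath(offset_constant_deg = 15, drift_deg_total = 10)
  raw <- simulate_pullback(ph, trajectory(length_mm = 1), cath,
                           tiny_acq(alines_per_frame = 32), seed = 5)
  opts <- noise_free_opts()
  cm <- estimate_cumulative(compute_stokes(raw, opts), opts)
  ang_before <- psoct:::cpp_rotation_angles(cm$C[, , , 3, 1])
  cc <- compensate_transmission(cm, opts)
  ang_after <- psoct:::cpp_rotation_angles(cc$C[, , , 3, 1])
  expect_equal(ang_after, ang_before, tolerance = 1e-8)
  expect_lt(max(cc$residual_asymmetry), 1e-3)
})

test_that("layer peeling inverts layered retarder stacks", {
  # homogeneous slab: constant retardance, constant orientation
  nz <- 40
  cm <- psoct:::cumulative_map_from_layers(rep(30, nz), rep(0.01, nz))
  lb <- peel_layers(cm, noise_free_opts())
  pix <- cm$acq$axial_pixel_um
  ret_exp <- 0.01 * 180 / pi * 100 / pix
  expect_equal(max(abs(lb$ret_deg100[, 1, 1] - ret_exp)) / ret_exp, 0,
               tolerance = 1e-6)
  expect_lt(max(orient_err(lb$orientation_raw_deg[, 1, 1], 30)), 0.1)

  # two layers: the second orientation is recovered unaffected by the first
  ori2 <- c(rep(0, 20), rep(90, 20))
  cm2 <- psoct:::cumulative_map_from_layers(ori2, rep(0.012, nz))
  lb2 <- peel_layers(cm2, noise_free_opts())
  expect_lt(max(orient_err(lb2$orientation_raw_deg[1:20, 1, 1], 0)), 1e-6)
  expect_lt(max(orient_err(lb2$orientation_raw_deg[21:40, 1, 1], 90)), 1e-6)

  # zero birefringence: retardance 0 and orientation masked
  cm3 <- psoct:::cumulative_map_from_layers(rep(0, nz), rep(0, nz))
  lb3 <- peel_layers(cm3, noise_free_opts())
  expect_equal(lb3$ret_deg100[, 1, 1], rep(0, nz))
  expect_false(any(lb3$mask))

  # masked gaps: peeling resumes with the per-pixel rate across the gap
  cm4 <- psoct:::cumulative_map_from_layers(rep(45, nz), rep(0.01, nz))
  cm4$valid[15:18, 1, 1] <- FALSE
  lb4 <- peel_layers(cm4, noise_free_opts())
  expect_false(any(lb4$mask[15:18, 1, 1]))
  expect_equal(lb4$ret_deg100[19, 1, 1], ret_exp, tolerance = 1e-6)
  expect_lt(max(orient_err(lb4$orientation_raw_deg[c(14, 19, 30), 1, 1], 45)),
            1e-6)
})

test_that("guide-star offsets are zero without transmission effects", {
  fx <- slab_fixture()
  lb <- fx$lb
  expect_lt(max(abs(lb$sheath_offset_deg)), 1e-6)
  d <- orient_err(lb$orientation_absolute_deg, lb$orientation_apparent_deg)
  expect_lt(max(d[lb$mask]), 1e-6)
})

test_that("a constant 25-degree offset is recovered within half a degree", {
  ph <- slab_phantom()
  cath <- quiet_cath(offset_constant_deg = 25)
  raw <- simulate_pullback(ph, trajectory(length_mm = 1), cath, tiny_acq(),
                           seed = 6)
  lb <- reconstruct_pullback(raw, noise_free_opts())
  expect_lt(max(abs(lb$sheath_offset_deg - 25)), 0.5)
  tz <- tissue_depths(raw)
  m <- lb$mask[tz, , ]
  err <- orient_err(lb$orientation_absolute_deg[tz, , ],
                    raw$truth$orientation_deg[1, 1])
  expect_lt(max(err[m]), 0.5)
  # and the uncorrected apparent orientation carries the offset
  err_app <- orient_err(lb$orientation_apparent_deg[tz, , ],
                        raw$truth$orientation_deg[1, 1])
  expect_gt(min(err_app[m]), 24)
})

test_that("offset recovery improves with sheath retardance", {
  ph <- slab_phantom()
  acq <- acq_config(alines_per_frame = 32, imaging_depth_mm = 0.2,
                    speckle = TRUE, detector_noise_sd = 0.1)
  errs <- matrix(NA_real_, 4, 2)
  for (s in 1:4) {
    for (i in 1:2) {
      cath <- catheter_model(sheath_retardance = c(0.2, 0.5)[i],
                             offset_amplitude_deg = 30, drift_deg_total = 0)
      raw <- simulate_pullback(ph, trajectory(length_mm = 0.6), cath, acq,
                               seed = 50 + s)
      lb <- reconstruct_pullback(raw, recon_options(offset_smooth_window = 5))
      errs[s, i] <- sqrt(mean((lb$sheath_offset_deg - raw$truth_offset_deg)^2))
    }
  }
  expect_lt(mean(errs[, 2]), mean(errs[, 1]))
})

test_that("the negative-birefringence flag shifts orientations by 90 degrees", {
  fx <- slab_fixture()
  raw <- fx$raw
  lb_neg <- reconstruct_pullback(raw, noise_free_opts(negative_birefringence = TRUE))
  lb_pos <- reconstruct_pullback(raw, noise_free_opts(negative_birefringence = FALSE))
  d <- (lb_neg$orientation_absolute_deg - lb_pos$orientation_absolute_deg) %% 180
  expect_equal(range(d[lb_neg$mask]), c(90, 90), tolerance = 1e-9)
})

test_that("multi-bin reconstruction averages bins consistently", {
  ph <- slab_phantom()
  acq <- tiny_acq(alines_per_frame = 32, spectral_bins = 3,
                  spectral_system_deg = 5)
  raw <- simulate_pullback(ph, trajectory(length_mm = 0.6), quiet_cath(), acq,
                           seed = 8)
  expect_equal(dim(raw$Eh)[4], 3L)
  lb <- reconstruct_pullback(raw, noise_free_opts())
  tz <- tissue_depths(raw)
  m <- lb$mask[tz, , ]
  err <- orient_err(lb$orientation_absolute_deg[tz, , ],
                    raw$truth$orientation_deg[1, 1])
  # per-bin offsets are +/-5 and 0 degrees; the guide star removes each
  expect_lt(mean(err[m]), 0.5)
})
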