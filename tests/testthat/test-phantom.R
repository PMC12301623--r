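# Phantom construction, MRI rendering and ground-truth maps.

test_that("the default phantom realizes the configured slab stack", {
  ph <- build_dbs_phantom(phantom_config(), seed = 1)
  cfg <- ph$config
  zc <- (seq_len(dim(ph$labels)[3]) - 0.5) * cfg$voxel_mm
  mid <- ceiling(dim(ph$labels)[1] / 2)
  col <- ph$labels[mid, mid, ]
  expect_equal(unique(col[zc < 2]), 1L)
  expect_equal(unique(col[zc > 2 & zc < 10]), 2L)
  expect_equal(unique(col[zc > 10 & zc < 13]), 3L)
  expect_equal(unique(col[zc > 13 & zc < 15]), 4L)
  expect_equal(unique(col[zc > 15]), 3L)
  # birefringence zero on grey-matter classes, positive on fiber classes
  expect_true(all(ph$dn[ph$labels %in% c(1L, 3L)] == 0))
  expect_true(all(ph$dn[ph$labels %in% c(2L, 4L)] > 0))
  # unit fiber vectors wherever birefringent
  idx <- which(ph$dn > 0)
  f2 <- ph$fiber[, , , 1]^2 + ph$fiber[, , , 2]^2 + ph$fiber[, , , 3]^2
  expect_equal(range(f2[idx]), c(1, 1), tolerance = 1e-9)
})

test_that("degenerate layer tables build or fail as specified", {
  layers <- data.frame(name = "gm", class = 1L, z0_mm = 0, z1_mm = 10, dn = 0,
                       fiber_mode = "none", theta_deg = NA,
                       fx = NA, fy = NA, fz = NA)
  ph <- build_dbs_phantom(phantom_config(length_mm = 10, layers = layers))
  expect_true(all(ph$dn == 0))
  bad <- layers; bad$z1_mm <- 8  # uncovered gap 8..10
  expect_error(phantom_config(length_mm = 10, layers = bad), "gap")
  bad2 <- layers; bad2$z1_mm <- 12  # exceeds the phantom
  expect_error(phantom_config(length_mm = 10, layers = bad2), "out of the phantom range")
})

test_that("phantom builds are deterministic for a given seed", {
  a <- build_dbs_phantom(phantom_config(dn_noise_sd = 0.05), seed = 42)
  b <- build_dbs_phantom(phantom_config(dn_noise_sd = 0.05), seed = 42)
  expect_identical(a$dn, b$dn)
  expect_identical(a$labels, b$labels)
  expect_identical(a$fiber, b$fiber)
  c <- build_dbs_phantom(phantom_config(dn_noise_sd = 0.05), seed = 43)
  expect_false(identical(a$dn, c$dn))
})

test_that("MRI rendering is an exact partial-volume box average", {
  # pure and half-and-half voxels, noise off; boundary at 0.855 mm sits
  # halfway through the second 0.57 mm voxel
  layers <- data.frame(
    name = c("gm", "wm"), class = c(1L, 2L),
    z0_mm = c(0, 0.855), z1_mm = c(0.855, 2.28), dn = c(0, 2e-4),
    fiber_mode = c("none", "apparent"), theta_deg = c(NA, 0),
    fx = NA, fy = NA, fz = NA)
  cfg <- phantom_config(voxel_mm = 0.057, lateral_mm = 1.14, length_mm = 2.28,
                        layers = layers)
  ph <- build_dbs_phantom(cfg)
  mri <- render_mri(ph, noise_sd = 0)
  im <- cfg$mri_intensity
  expect_equal(mri$data[1, 1, 1], im[1], tolerance = 1e-12)   # pure grey
  expect_equal(mri$data[1, 1, 2], mean(im[1:2]), tolerance = 1e-12)  # straddling
  expect_equal(mri$data[1, 1, 3], im[2], tolerance = 1e-12)   # pure white

  # brute-force overlap oracle on a random label grid
  set.seed(9)
  labs <- array(sample(1:4, 6 * 6 * 8, replace = TRUE), c(6, 6, 8))
  gm_layer <- data.frame(name = "gm", class = 1L, z0_mm = 0, z1_mm = 2.4,
                         dn = 0, fiber_mode = "none", theta_deg = NA,
                         fx = NA, fy = NA, fz = NA)
  ph2 <- build_dbs_phantom(phantom_config(voxel_mm = 0.3, lateral_mm = 1.8,
                                          length_mm = 2.4, layers = gm_layer))
  ph2$labels <- labs
  vox <- 0.7
  mri2 <- render_mri(ph2, voxel_mm = vox, noise_sd = 0)
  img <- array(ph2$config$mri_intensity[labs], dim(labs))
  pv <- 0.3
  oracle <- function(i, j, k) {
    tot <- 0; wsum <- 0
    for (a in 1:6) for (b in 1:6) for (cc in 1:8) {
      ov <- function(m, n) {
        max(0, min(m * vox, n * pv) - max((m - 1) * vox, (n - 1) * pv))
      }
      w <- ov(i, a) * ov(j, b) * ov(k, cc)
      tot <- tot + w * img[a, b, cc]; wsum <- wsum + w
    }
    tot / wsum
  }
  for (idx in list(c(1, 1, 1), c(2, 2, 2), c(3, 1, 3), c(2, 3, 4))) {
    expect_equal(mri2$data[idx[1], idx[2], idx[3]],
                 oracle(idx[1], idx[2], idx[3]), tolerance = 1e-9)
  }
})

test_that("MRI rendering conserves the volume-weighted mean intensity", {
  ph <- build_dbs_phantom(phantom_config(), seed = 1)
  mri <- render_mri(ph, noise_sd = 0)
  img_mean <- mean(ph$config$mri_intensity[ph$labels])
  w_mean <- sum(mri$data * mri$coverage) / sum(mri$coverage)
  expect_equal(w_mean, img_mean, tolerance = 1e-6)
})

test_that("the default MRI profile has two plateaus with single-voxel ramps", {
  ph <- build_dbs_phantom(phantom_config(), seed = 1)
  mri <- render_mri(ph, noise_sd = 0)
  mid <- ceiling(dim(mri$data)[1] / 2)
  prof <- mri$data[mid, mid, ]
  im <- sort(unique(ph$config$mri_intensity))
  on_plateau <- abs(prof - im[1]) < 1e-9 | abs(prof - im[2]) < 1e-9
  # four class boundaries -> at most four intermediate (ramp) voxels
  expect_lte(sum(!on_plateau), 4)
  runs <- rle(!on_plateau)
  expect_true(all(runs$lengths[runs$values] <= 1))
})

test_that("ground-truth maps follow the beam-projection closed form", {
  acq <- tiny_acq()
  traj <- trajectory(length_mm = 4)
  # grey matter only: zero retardance, undefined orientation
  tr <- true_maps_along_trajectory(gm_phantom(), traj, acq)
  expect_true(all(tr$ret_deg100 == 0))
  expect_true(all(is.na(tr$orientation_deg)))
  expect_false(any(tr$defined))
  # circumferential fibers: 0 degrees at every azimuth
  tr <- true_maps_along_trajectory(slab_phantom(theta_deg = 0), traj, acq)
  expect_true(all(tr$orientation_deg == 0))
  expect_true(all(tr$defined))
  expect_equal(dim(tr$ret_deg100), c(20, 32))
  # lab-fixed horizontal fiber: independent projection formula per azimuth
  tr <- true_maps_along_trajectory(tract_phantom(), traj, acq)
  a <- tr$pair_azimuth_deg * pi / 180
  scale <- sin(a)^2
  lam_um <- acq$center_wavelength_nm / 1000
  ret_exp <- 2 * pi * 5e-4 * scale * 200 / lam_um * 180 / pi
  expect_equal(tr$ret_deg100[1, ], ret_exp, tolerance = 1e-9)
  expect_true(all(tr$orientation_deg[1, tr$defined[1, ]] %in% c(0)))
  expect_equal(tr$defined[1, ], sqrt(scale) >= 1e-6)
  # beam-parallel azimuths yield no measurable birefringence
  expect_true(all(tr$ret_deg100[1, !tr$defined[1, ]] < 1e-12))
})

test_that("trajectories outside the phantom are rejected", {
  ph <- slab_phantom(length_mm = 6)
  expect_error(true_maps_along_trajectory(ph, trajectory(length_mm = 30), tiny_acq()),
               "exits")
  expect_error(trajectory(direction = c(1, 0, 0)), "z grid axis")
})
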