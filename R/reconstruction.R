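# Inversion of the acquisition: Stokes estimation, cumulative rotation
# retrieval, transmission compensation, layer peeling, guide-star correction.

#' Reconstruction options
#'
#' @param filter_axial_sigma Gaussian filter sigma along depth, in depth
#'   pixels (0 disables).
#' @param filter_lateral_sigma Gaussian filter sigma along A-line pairs
#'   (circular over the frame), in pairs (0 disables).
#' @param dop_threshold Degree-of-polarization mask threshold.
#' @param ret_floor_deg100 Local-retardance mask floor, degrees per 100 um
#'   (double-pass); orientations below it are reported as undefined.
#' @param ortho_max_dev_deg Maximum tolerated deviation of a measured state
#'   pair from Poincare orthogonality before the pixel is masked.
#' @param compensate Run the transmission-compensation stage.
#' @param comp_window_pairs,comp_window_frames Smoothing window (A-line
#'   pairs x frames) over which the cumulative rotations are averaged before
#'   estimating the per-A-line correction.
#' @param comp_max_depths Depth subsample cap used in the asymmetry
#'   objective.
#' @param comp_lambda Small-magnitude tie-break regularizer on the
#'   correction rotation vector.
#' @param local_axial_sigma,local_lateral_sigma Gaussian smoothing of the
#'   local retardance *vector* field after peeling (axial in pixels,
#'   lateral in A-line pairs, 0 disables). Averaging the equatorial
#'   rotation vectors, not the angles, suppresses the retrograde axis
#'   flips that differential noise causes when the per-pixel retardance is
#'   small.
#' @param offset_smooth_window Circular smoothing window (in A-line pairs)
#'   for the guide-star offset series.
#' @param negative_birefringence Interpret tissue as negatively birefringent
#'   (reported fiber orientations are the measured retarder axes shifted by
#'   90 degrees). `NULL` takes the convention recorded in the pullback.
#' @return A list of class `recon_options`.
#' @export
recon_options <- function(filter_axial_sigma = 1, filter_lateral_sigma = 2,
                          dop_threshold = 0.7, ret_floor_deg100 = 5,
                          ortho_max_dev_deg = 25,
                          compensate = TRUE, comp_window_pairs = 5,
                          comp_window_frames = 3, comp_max_depths = 60,
                          comp_lambda = 1e-3,
                          local_axial_sigma = 5, local_lateral_sigma = 2,
                          offset_smooth_window = 15,
                          negative_birefringence = NULL) {
  stopifnot(filter_axial_sigma >= 0, filter_lateral_sigma >= 0,
            dop_threshold >= 0, dop_threshold <= 1, ret_floor_deg100 >= 0,
            comp_window_pairs >= 1, comp_window_frames >= 1,
            comp_max_depths >= 4, offset_smooth_window >= 1,
            local_axial_sigma >= 0, local_lateral_sigma >= 0)
  structure(list(filter_axial_sigma = filter_axial_sigma,
                 filter_lateral_sigma = filter_lateral_sigma,
                 dop_threshold = dop_threshold,
                 ret_floor_deg100 = ret_floor_deg100,
                 ortho_max_dev_deg = ortho_max_dev_deg,
                 compensate = compensate,
                 comp_window_pairs = comp_window_pairs,
                 comp_window_frames = comp_window_frames,
                 comp_max_depths = comp_max_depths,
                 comp_lambda = comp_lambda,
                 local_axial_sigma = local_axial_sigma,
                 local_lateral_sigma = local_lateral_sigma,
                 offset_smooth_window = offset_smooth_window,
                 negative_birefringence = negative_birefringence),
            class = "recon_options")
}

gauss_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k / sum(k)
}

# separable smoothing of a [nz, np, nf] array: reflected along depth,
# circular along the A-line-pair (azimuth) dimension
smooth_depth_pair <- function(arr, sigma_z, sigma_p) {
  d <- dim(arr)
  if (sigma_z > 0) {
    k <- gauss_kernel(sigma_z)
    r <- (length(k) - 1) / 2
    out <- array(0, d)
    for (t in seq_along(k)) {
      off <- t - r - 1
      idx <- seq_len(d[1]) + off
      idx[idx < 1] <- 2 - idx[idx < 1]          # reflect
      idx[idx > d[1]] <- 2 * d[1] - idx[idx > d[1]]
      out <- out + k[t] * arr[idx, , , drop = FALSE]
    }
    arr <- out
  }
  if (sigma_p > 0 && d[2] > 1) {
    k <- gauss_kernel(sigma_p)
    r <- (length(k) - 1) / 2
    out <- array(0, d)
    for (t in seq_along(k)) {
      off <- t - r - 1
      idx <- ((seq_len(d[2]) + off - 1) %% d[2]) + 1  # circular
      out <- out + k[t] * arr[, idx, , drop = FALSE]
    }
    arr <- out
  }
  arr
}

#' Filtered Stokes volume from raw fields
#'
#' Applies [stokes_from_fields()] pixel-wise per detection-channel pair,
#' pairs adjacent A-lines into (state-1, state-2) tuples, smooths the
#' unnormalized Stokes components with a separable Gaussian (reflected along
#' depth, circular along azimuth) and renormalizes. The degree of
#' polarization of the filtered states is retained for masking.
#'
#' @param raw A `pullback_raw`.
#' @param opts A [recon_options()].
#' @param bin Spectral bin index.
#' @return A list of class `stokes_volume` with unit-norm state arrays `S1`,
#'   `S2` of dim `[depth, pair, frame, 3]`, intensities `I1`, `I2`, and
#'   `dop1`, `dop2`.
#' @export
compute_stokes <- function(raw, opts = recon_options(), bin = 1L) {
  stopifnot(inherits(raw, "pullback_raw"))
  nA <- dim(raw$Eh)[2]
  if (nA %% 2 == 1) {
    warning("odd A-line count: dropping the last A-line of every frame")
    nA <- nA - 1
  }
  i1 <- seq(1, nA, by = 2)
  i2 <- seq(2, nA, by = 2)
  res <- list()
  for (s in 1:2) {
    idx <- if (s == 1) i1 else i2
    h <- raw$Eh[, idx, , bin, drop = FALSE]
    v <- raw$Ev[, idx, , bin, drop = FALSE]
    d3 <- dim(h)[1:3]
    h <- array(h, d3); v <- array(v, d3)
    I <- Mod(h)^2 + Mod(v)^2
    Q <- Mod(h)^2 - Mod(v)^2
    w <- Conj(h) * v
    U <- 2 * Re(w)
    V <- -2 * Im(w)
    sz <- opts$filter_axial_sigma; sp <- opts$filter_lateral_sigma
    If <- smooth_depth_pair(I, sz, sp)
    Qf <- smooth_depth_pair(Q, sz, sp)
    Uf <- smooth_depth_pair(U, sz, sp)
    Vf <- smooth_depth_pair(V, sz, sp)
    nrm <- sqrt(Qf^2 + Uf^2 + Vf^2)
    dop <- nrm / pmax(If, .Machine$double.eps)
    S <- array(0, c(d3, 3))
    S[, , , 1] <- Qf / pmax(nrm, .Machine$double.eps)
    S[, , , 2] <- Uf / pmax(nrm, .Machine$double.eps)
    S[, , , 3] <- Vf / pmax(nrm, .Machine$double.eps)
    res[[s]] <- list(S = S, I = If, dop = dop)
  }
  structure(list(S1 = res[[1]]$S, S2 = res[[2]]$S,
                 I1 = res[[1]]$I, I2 = res[[2]]$I,
                 dop1 = res[[1]]$dop, dop2 = res[[2]]$dop,
                 in1 = c(1, 0, 0), in2 = c(0, 1, 0),
                 raw_meta = raw[c("sheath_band", "n_pre", "n_sheath",
                                  "pitch_mm", "frames", "phantom_sign")],
                 acq = raw$acq, catheter = raw$catheter),
            class = "stokes_volume")
}

#' Cumulative rotation map from a Stokes volume
#'
#' Per pixel, the unique rotation mapping the known input state pair onto
#' the measured pair (orthogonalized), i.e. the cumulative
#' retardance/rotation matrix of sheath + tissue + transmission. Pixels
#' whose filtered degree of polarization falls below the threshold, or
#' whose measured pair deviates too far from orthogonality, are masked
#' rather than raised.
#'
#' @param sv A `stokes_volume`.
#' @param opts A [recon_options()].
#' @return A list of class `cumulative_map` with `C` (array
#'   `[3, 3, depth, pair, frame]`) and `valid` (`[depth, pair, frame]`).
#' @export
estimate_cumulative <- function(sv, opts = recon_options()) {
  stopifnot(inherits(sv, "stokes_volume"))
  d3 <- dim(sv$S1)[1:3]
  b1 <- sv$S1; b2 <- sv$S2
  dot <- b1[, , , 1] * b2[, , , 1] + b1[, , , 2] * b2[, , , 2] + b1[, , , 3] * b2[, , , 3]
  dev <- abs(90 - acos(pmax(-1, pmin(1, dot))) * 180 / pi)
  # orthogonalize state 2 against state 1
  o2 <- array(0, dim(b2))
  for (k in 1:3) o2[, , , k] <- b2[, , , k] - dot * b1[, , , k]
  n2 <- sqrt(o2[, , , 1]^2 + o2[, , , 2]^2 + o2[, , , 3]^2)
  for (k in 1:3) o2[, , , k] <- o2[, , , k] / pmax(n2, .Machine$double.eps)
  # third column: b1 x o2
  c3 <- array(0, dim(b1))
  c3[, , , 1] <- b1[, , , 2] * o2[, , , 3] - b1[, , , 3] * o2[, , , 2]
  c3[, , , 2] <- b1[, , , 3] * o2[, , , 1] - b1[, , , 1] * o2[, , , 3]
  c3[, , , 3] <- b1[, , , 1] * o2[, , , 2] - b1[, , , 2] * o2[, , , 1]
  # with input triad = standard basis, C's columns are (b1, o2, b1 x o2)
  C <- array(0, c(3, 3, d3))
  for (i in 1:3) {
    C[i, 1, , , ] <- b1[, , , i]
    C[i, 2, , , ] <- o2[, , , i]
    C[i, 3, , , ] <- c3[, , , i]
  }
  valid <- sv$dop1 >= opts$dop_threshold & sv$dop2 >= opts$dop_threshold &
    dev <= opts$ortho_max_dev_deg & is.finite(dot) & n2 > 1e-9
  structure(list(C = C, valid = valid, intensity = (sv$I1 + sv$I2) / 2,
                 raw_meta = sv$raw_meta, acq = sv$acq, catheter = sv$catheter),
            class = "cumulative_map")
}

#' Transmission compensation by symmetry restoration
#'
#' Round-trip measurements through linearly retarding tissue are
#' D-transpose symmetric; system and catheter transmission of the assumed
#' reciprocal form preserves that symmetry, while estimation noise breaks
#' it. Per A-line pair this stage estimates a correction rotation `V`
#' (axis-angle parameterization, initialized at the previous A-line's
#' solution) minimizing the summed squared Frobenius asymmetry of
#' `Chat(z) = dT(V)^-1 C(z) V^-1` over valid depths of a window-averaged
#' rotation stack, with a small-magnitude tie-break regularizer, and
#' applies it. The mean residual asymmetry is stored as a quality metric.
#'
#' @param cm A `cumulative_map`.
#' @param opts A [recon_options()].
#' @return The compensated `cumulative_map`, with `vhat` (`[3, pair, frame]`
#'   correction rotation vectors) and `residual_asymmetry` (`[pair, frame]`).
#' @export
compensate_transmission <- function(cm, opts = recon_options()) {
  stopifnot(inherits(cm, "cumulative_map"))
  d <- dim(cm$valid)
  nz <- d[1]; np <- d[2]; nf <- d[3]
  vhat <- array(0, c(3, np, nf))
  resid <- matrix(NA_real_, np, nf)
  if (!opts$compensate) {
    cm$vhat <- vhat
    cm$residual_asymmetry <- residual_asymmetry_map(cm)
    return(cm)
  }
  wp <- opts$comp_window_pairs; wf <- opts$comp_window_frames
  hp <- (wp - 1) %/% 2; hf <- (wf - 1) %/% 2
  n_fallback <- 0L
  for (f in seq_len(nf)) {
    fr <- max(1, f - hf):min(nf, f + hf)
    prev <- if (f == 1) c(0, 0, 0) else vhat[, 1, f - 1]
    for (p in seq_len(np)) {
      pr <- (((p - hp):(p + hp) - 1) %% np) + 1
      Cw <- cm$C[, , , pr, fr, drop = FALSE]
      dim(Cw) <- c(3, 3, nz, length(pr) * length(fr))
      Cavg <- rowMeans(Cw, dims = 3)
      vw <- cm$valid[, pr, fr, drop = FALSE]
      vavg <- apply(vw, 1, mean) >= 0.5
      zi <- which(vavg)
      if (length(zi) > opts$comp_max_depths) {
        zi <- zi[round(seq(1, length(zi), length.out = opts$comp_max_depths))]
      }
      if (length(zi) < 4) {
        vhat[, p, f] <- prev
        n_fallback <- n_fallback + 1L
      } else {
        Csub <- Cavg[, , zi, drop = FALSE]
        vsub <- rep(TRUE, length(zi))
        fn <- function(v) {
          cpp_asym_cost(Csub, vsub, v) + opts$comp_lambda * sum(v^2)
        }
        o <- stats::optim(prev, fn, method = "Nelder-Mead",
                          control = list(maxit = 300, reltol = 1e-10))
        if (o$convergence != 0 && p > 1) {
          vhat[, p, f] <- vhat[, p - 1, f]
          n_fallback <- n_fallback + 1L
        } else {
          vhat[, p, f] <- o$par
        }
      }
      prev <- vhat[, p, f]
      Ch <- cpp_apply_compensation(cm$C[, , , p, f], vhat[, p, f])
      cm$C[, , , p, f] <- Ch
      resid[p, f] <- cpp_mean_asymmetry(Ch, cm$valid[, p, f])
    }
  }
  if (n_fallback > 0) {
    warning(n_fallback, " A-line(s) fell back to the neighboring correction")
  }
  cm$vhat <- vhat
  cm$residual_asymmetry <- resid
  cm
}

# Build a cumulative_map directly from per-depth layer parameters (one
# A-line), bypassing the field simulator: C(z) = P(z) dT(P(z)) with
# P(z) = L1 ... Lz. Used by tests and examples of the peeling recursion.
cumulative_map_from_layers <- function(orientation_deg, retardance,
                                       acq = acq_config()) {
  stopifnot(length(orientation_deg) == length(retardance))
  nz <- length(retardance)
  C <- array(0, c(3, 3, nz, 1, 1))
  P <- diag(3)
  for (z in seq_len(nz)) {
    P <- P %*% linear_retarder(orientation_deg[z], retardance[z])
    C[, , z, 1, 1] <- P %*% d_transpose(P)
  }
  structure(list(C = C, valid = array(TRUE, c(nz, 1, 1)),
                 intensity = array(1, c(nz, 1, 1)),
                 raw_meta = list(sheath_band = integer(0), n_pre = 0L,
                                 n_sheath = 0L, pitch_mm = 0.2, frames = 1L,
                                 phantom_sign = 1),
                 acq = acq, catheter = catheter_model()),
            class = "cumulative_map")
}

residual_asymmetry_map <- function(cm) {
  d <- dim(cm$valid)
  out <- matrix(NA_real_, d[2], d[3])
  for (f in seq_len(d[3]))
    for (p in seq_len(d[2]))
      out[p, f] <- cpp_mean_asymmetry(cm$C[, , , p, f], cm$valid[, p, f])
  out
}

#' Depth-resolved layer peeling
#'
#' Inverts the cumulative map into local properties by correcting, depth by
#' depth, for the preceding linearly retarding layers (one pixel thick):
#' `N(z+1) = C(z+1) C(z)^-1`, local double-pass angle = rotation angle of
#' `N`, local retardance = half of it, local Poincare axis = the rebuilt
#' one-way product `P(z)^-1` applied to the axis of `N` and projected to the
#' equator, apparent orientation = halved axis azimuth, and
#' `P(z+1) = P(z) . linear_retarder(orientation, delta)`. Masked depths are
#' skipped with `P` carried forward; the retardance across a gap is reported
#' as a per-pixel rate.
#'
#' @param cm A (compensated) `cumulative_map`.
#' @param opts A [recon_options()].
#' @return A list of class `local_biref_map` with `ret_deg100`,
#'   `orientation_raw_deg` (measured retarder-axis orientation, degrees in
#'   `[0, 180)`), `mask` (all `[depth, pair, frame]`), and metadata.
#' @export
peel_layers <- function(cm, opts = recon_options()) {
  stopifnot(inherits(cm, "cumulative_map"))
  d <- dim(cm$valid)
  nz <- d[1]; np <- d[2]; nf <- d[3]
  pix_um <- cm$acq$axial_pixel_um
  ret <- array(NA_real_, d)
  ori <- array(NA_real_, d)
  ok <- array(FALSE, d)
  for (f in seq_len(nf)) {
    for (p in seq_len(np)) {
      r <- cpp_peel(cm$C[, , , p, f], cm$valid[, p, f])
      ret[, p, f] <- r$delta * (180 / pi) * (100 / pix_um)
      ori[, p, f] <- (r$az2 / 2 * 180 / pi) %% 180
      ok[, p, f] <- r$ok
    }
  }
  if (opts$local_axial_sigma > 0 || opts$local_lateral_sigma > 0) {
    # average the equatorial local rotation vectors, not the angles:
    # robust against retrograde axis flips of near-zero local retarders
    a2 <- 2 * ori * pi / 180
    w <- ifelse(ok & is.finite(ret) & is.finite(a2), 1, 0)
    vx <- ifelse(w > 0, ret * cos(a2), 0)
    vy <- ifelse(w > 0, ret * sin(a2), 0)
    sx <- smooth_depth_pair(vx, opts$local_axial_sigma, opts$local_lateral_sigma)
    sy <- smooth_depth_pair(vy, opts$local_axial_sigma, opts$local_lateral_sigma)
    sw <- smooth_depth_pair(w, opts$local_axial_sigma, opts$local_lateral_sigma)
    ret <- ifelse(sw > 0.25, sqrt(sx^2 + sy^2) / pmax(sw, 1e-12), NA_real_)
    ori <- ifelse(sw > 0.25, (atan2(sy, sx) / 2 * 180 / pi) %% 180, NA_real_)
    ok <- ok & sw > 0.25
  }
  mask <- ok & is.finite(ret) & ret >= opts$ret_floor_deg100 & is.finite(ori)
  structure(list(ret_deg100 = ret, orientation_raw_deg = ori, mask = mask,
                 valid = cm$valid, intensity = cm$intensity,
                 residual_asymmetry = cm$residual_asymmetry,
                 raw_meta = cm$raw_meta, acq = cm$acq, catheter = cm$catheter),
            class = "local_biref_map")
}

# circular running mean of an orientation series (period 180), uniform
# window, circular along the series; NAs carry zero weight and are filled
smooth_orientation_series <- function(theta_deg, window) {
  n <- length(theta_deg)
  w <- ifelse(is.finite(theta_deg), 1, 0)
  a <- ifelse(is.finite(theta_deg), 2 * theta_deg * pi / 180, 0)
  cs <- w * cos(a); sn <- w * sin(a)
  r <- max(0L, (as.integer(window) - 1L) %/% 2L)
  csum <- snum <- wsum <- numeric(n)
  for (off in (-r):r) {
    idx <- ((seq_len(n) + off - 1) %% n) + 1
    csum <- csum + cs[idx]; snum <- snum + sn[idx]; wsum <- wsum + w[idx]
  }
  out <- ifelse(wsum > 0, atan2(snum, csum) / 2 * 180 / pi, NA_real_)
  if (anyNA(out) && any(!is.na(out))) {
    # widen to the global circular mean where the window saw nothing
    gm <- atan2(sum(sn), sum(cs)) / 2 * 180 / pi
    out[is.na(out)] <- gm
  }
  out %% 180
}

#' Guide-star correction of the optic-axis orientation
#'
#' Uses the birefringent catheter sheath as an orientation reference: per
#' A-line the apparent sheath orientation (circular mean over the sheath
#' depth band, period 180) minus the known sheath orientation gives the
#' transmission offset, which is circularly smoothed along azimuth and
#' subtracted from the tissue orientations to obtain absolute orientation.
#' A-lines without a detected sheath inherit the smoothed neighborhood
#' estimate and are flagged.
#'
#' @param lb A `local_biref_map` from [peel_layers()].
#' @param sheath_band Depth indices of the sheath; defaults to the band
#'   recorded in the pullback metadata.
#' @param sheath_orientation_deg Known sheath orientation in the probe
#'   frame; defaults to the catheter model value.
#' @param opts A [recon_options()].
#' @return The `local_biref_map` with added `orientation_apparent_deg`,
#'   `orientation_absolute_deg`, `sheath_offset_deg` (`[pair, frame]`), and
#'   `sheath_flagged`.
#' @export
guide_star_correct <- function(lb, sheath_band = NULL,
                               sheath_orientation_deg = NULL,
                               opts = recon_options()) {
  stopifnot(inherits(lb, "local_biref_map"))
  if (is.null(sheath_band)) sheath_band <- lb$raw_meta$sheath_band
  if (is.null(sheath_orientation_deg)) {
    sheath_orientation_deg <- lb$catheter$sheath_orientation_deg
  }
  d <- dim(lb$mask)
  np <- d[2]; nf <- d[3]
  if (max(sheath_band) > d[1]) stop("sheath band outside the depth range")
  # mean measured sheath retardance must clear the floor (guide star visible)
  sret <- mean(lb$ret_deg100[sheath_band, , ], na.rm = TRUE)
  if (!is.finite(sret) || sret < opts$ret_floor_deg100 / 2) {
    stop("sheath retardance not detectable: guide star unavailable")
  }
  flip <- negative_flip_deg(lb, opts)
  offset <- matrix(NA_real_, np, nf)
  flagged <- matrix(FALSE, np, nf)
  for (f in seq_len(nf)) {
    for (p in seq_len(np)) {
      th <- lb$orientation_raw_deg[sheath_band, p, f]
      m <- lb$mask[sheath_band, p, f]
      if (sum(m) >= max(2, length(sheath_band) %/% 4)) {
        app <- circ_mean_180(th[m])
        offset[p, f] <- circ_diff_180(app, sheath_orientation_deg)
      } else {
        flagged[p, f] <- TRUE
      }
    }
    offset[, f] <- smooth_offset_series(offset[, f], opts$offset_smooth_window)
  }
  lb$sheath_offset_deg <- offset
  lb$sheath_flagged <- flagged
  off3 <- aperm(array(offset, c(np, nf, d[1])), c(3, 1, 2))
  lb$orientation_apparent_deg <- (lb$orientation_raw_deg + flip) %% 180
  lb$orientation_absolute_deg <- (lb$orientation_raw_deg - off3 + flip) %% 180
  lb
}

negative_flip_deg <- function(lb, opts) {
  neg <- opts$negative_birefringence
  if (is.null(neg)) neg <- isTRUE(lb$raw_meta$phantom_sign < 0)
  if (neg) 90 else 0
}

# offsets live on (-90, 90]; smooth via the doubled-angle circular mean;
# an A-line series with no sheath estimate at all falls back to zero offset
smooth_offset_series <- function(off_deg, window) {
  if (all(!is.finite(off_deg))) return(rep(0, length(off_deg)))
  s <- smooth_orientation_series(off_deg %% 180, window)
  s[!is.finite(s)] <- 0
  d <- s
  d[d > 90] <- d[d > 90] - 180
  d
}

#' Full reconstruction chain
#'
#' Runs [compute_stokes()], [estimate_cumulative()],
#' [compensate_transmission()], [peel_layers()] and [guide_star_correct()]
#' per spectral bin, then combines bins (mean retardance, circular-mean
#' orientations, majority mask).
#'
#' @param raw A `pullback_raw`.
#' @param opts A [recon_options()].
#' @return A `local_biref_map` with absolute orientations.
#' @export
reconstruct_pullback <- function(raw, opts = recon_options()) {
  bins <- dim(raw$Eh)[4]
  maps <- vector("list", bins)
  for (b in seq_len(bins)) {
    sv <- compute_stokes(raw, opts, bin = b)
    cm <- estimate_cumulative(sv, opts)
    cm <- compensate_transmission(cm, opts)
    lb <- peel_layers(cm, opts)
    maps[[b]] <- guide_star_correct(lb, opts = opts)
  }
  if (bins == 1) return(maps[[1]])
  out <- maps[[1]]
  d <- dim(out$mask)
  ret <- array(0, d); msum <- array(0L, d)
  ca <- array(0, d); sa <- array(0, d)
  cb <- array(0, d); sb <- array(0, d)
  for (b in seq_len(bins)) {
    m <- maps[[b]]
    ret <- ret + ifelse(is.finite(m$ret_deg100), m$ret_deg100, 0)
    msum <- msum + m$mask
    aa <- 2 * m$orientation_absolute_deg * pi / 180
    ap <- 2 * m$orientation_apparent_deg * pi / 180
    ca <- ca + ifelse(is.finite(aa), cos(aa), 0)
    sa <- sa + ifelse(is.finite(aa), sin(aa), 0)
    cb <- cb + ifelse(is.finite(ap), cos(ap), 0)
    sb <- sb + ifelse(is.finite(ap), sin(ap), 0)
  }
  out$ret_deg100 <- ret / bins
  out$mask <- msum > bins / 2
  out$orientation_absolute_deg <- (atan2(sa, ca) / 2 * 180 / pi) %% 180
  out$orientation_apparent_deg <- (atan2(sb, cb) / 2 * 180 / pi) %% 180
  out
}
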