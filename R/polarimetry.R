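#' @useDynLib psoct, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats optim rnorm runif approx
#' @importFrom utils modifyList
NULL

# ---------------------------------------------------------------------------
# Poincare-sphere conventions used throughout the package
#
#   - A polarization state is a Stokes vector s = (q, u, v) of unit norm
#     (when the intensity is positive), living on the Poincare sphere.
#   - A pure retarder is a proper rotation of s; a *linear* retarder with
#     physical fast-axis orientation theta (degrees, mod 180) and retardance
#     delta (rad) rotates by delta about the equatorial axis
#     (cos 2*theta, sin 2*theta, 0): physical angles are halved azimuths.
#   - Handedness: from detected field amplitudes (h, v),
#       q = (|h|^2 - |v|^2)/I, u = 2 Re(Conj(h) v)/I, v = -2 Im(Conj(h) v)/I,
#     so the right-circular field (1, i)/sqrt(2) maps to (0, 0, -1).
#   - The reciprocity operator for round-trip measurements is
#     dT(A) = D A^T D with D = diag(1, 1, -1).
# ---------------------------------------------------------------------------

#' Construct a normalized polarization state
#'
#' Builds a Stokes vector on the Poincare sphere. When `intensity > 0` the
#' (q, u, v) components are normalized to unit Euclidean norm; a state with
#' zero intensity is flagged invalid and left unnormalized.
#'
#' @param q,u,v Stokes components (dimensionless).
#' @param intensity Total intensity, arbitrary units, must be >= 0.
#' @return A list of class `polarization_state` with fields `q`, `u`, `v`,
#'   `intensity`, `valid`.
#' @export
polarization_state <- function(q, u, v, intensity = 1) {
  stopifnot(is.numeric(q), is.numeric(u), is.numeric(v), intensity >= 0)
  n <- sqrt(q^2 + u^2 + v^2)
  valid <- intensity > 0 && n > 0
  if (valid) {
    q <- q / n; u <- u / n; v <- v / n
  }
  structure(list(q = q, u = u, v = v, intensity = intensity, valid = valid),
            class = "polarization_state")
}

state_vec <- function(s) {
  if (inherits(s, "polarization_state")) c(s$q, s$u, s$v) else as.numeric(s)
}

#' Validate a 3x3 rotation matrix
#'
#' Checks orthonormality and unit determinant within `tol`.
#'
#' @param m A 3x3 numeric matrix.
#' @param tol Numerical tolerance.
#' @return `TRUE` or `FALSE`.
#' @export
is_rotation3 <- function(m, tol = 1e-9) {
  is.matrix(m) && all(dim(m) == c(3, 3)) &&
    max(abs(crossprod(m) - diag(3))) < tol &&
    abs(det(m) - 1) < tol
}

#' Rotation about an axis through the origin
#'
#' Rodrigues rotation by `angle` radians about the (normalized) `axis`.
#'
#' @param axis Numeric 3-vector; normalized internally.
#' @param angle Rotation angle in radians.
#' @return A 3x3 rotation matrix.
#' @export
rot_axis_angle <- function(axis, angle) {
  n <- sqrt(sum(axis^2))
  stopifnot(is.finite(angle), n > 0)
  a <- axis / n
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Linear retarder parameters
#'
#' @param orientation_deg Fast-axis orientation in degrees, reduced mod 180.
#' @param retardance Retardance in radians, >= 0 and finite.
#' @return A list of class `linear_retarder_params`.
#' @export
linear_retarder_params <- function(orientation_deg, retardance) {
  stopifnot(is.finite(orientation_deg), is.finite(retardance), retardance >= 0)
  structure(list(orientation_deg = orientation_deg %% 180, retardance = retardance),
            class = "linear_retarder_params")
}

#' Rotation matrix of a linear retarder
#'
#' The retarder with fast-axis orientation `theta` (degrees) and retardance
#' `delta` (radians) is the rotation by `delta` about the equatorial Poincare
#' axis (cos 2 theta, sin 2 theta, 0). Zero retardance returns the identity.
#'
#' @param orientation_deg Fast-axis orientation in degrees (or a
#'   `linear_retarder_params` object, in which case `retardance` is ignored).
#' @param retardance Retardance in radians.
#' @return A 3x3 rotation matrix.
#' @export
linear_retarder <- function(orientation_deg, retardance = NULL) {
  if (inherits(orientation_deg, "linear_retarder_params")) {
    p <- orientation_deg
    orientation_deg <- p$orientation_deg
    retardance <- p$retardance
  }
  stopifnot(is.finite(retardance))
  if (retardance == 0) return(diag(3))
  a2 <- 2 * orientation_deg * pi / 180
  rot_axis_angle(c(cos(a2), sin(a2), 0), retardance)
}

#' Axis-angle (retardance vector) log of a rotation
#'
#' Inverts [retvec_to_rotation()]: returns the unit rotation axis and the
#' angle in `[0, pi]`. The identity returns angle 0 with axis (1, 0, 0) by
#' convention. At angle pi the axis sign is fixed by requiring the first
#' nonzero component to be positive.
#'
#' @param r A 3x3 rotation matrix.
#' @param linear_tol Tolerance on the third axis component below which the
#'   returned vector is flagged as a linear retarder.
#' @return A list of class `retardance_vector` with `axis` (unit 3-vector),
#'   `angle` (radians), and `linear` (logical).
#' @export
rotation_to_retvec <- function(r, linear_tol = 1e-6) {
  stopifnot(is_rotation3(r, tol = 1e-6))
  tr <- sum(diag(r))
  angle <- acos(max(-1, min(1, (tr - 1) / 2)))
  if (angle < 1e-12) {
    axis <- c(1, 0, 0)
    angle <- 0
  } else if (angle < pi - 1e-6) {
    axis <- c(r[3, 2] - r[2, 3], r[1, 3] - r[3, 1], r[2, 1] - r[1, 2]) / (2 * sin(angle))
    axis <- axis / sqrt(sum(axis^2))
  } else {
    n <- sqrt(pmax(0, (diag(r) + 1) / 2))
    i <- which.max(n)
    if (i == 1) {
      n[2] <- n[2] * sign_or_one(r[1, 2] + r[2, 1])
      n[3] <- n[3] * sign_or_one(r[1, 3] + r[3, 1])
    } else if (i == 2) {
      n[1] <- n[1] * sign_or_one(r[1, 2] + r[2, 1])
      n[3] <- n[3] * sign_or_one(r[2, 3] + r[3, 2])
    } else {
      n[1] <- n[1] * sign_or_one(r[1, 3] + r[3, 1])
      n[2] <- n[2] * sign_or_one(r[2, 3] + r[3, 2])
    }
    axis <- n / sqrt(sum(n^2))
    first <- axis[which(abs(axis) > 1e-9)[1]]
    if (first < 0) axis <- -axis
  }
  structure(list(axis = axis, angle = angle, linear = abs(axis[3]) <= linear_tol),
            class = "retardance_vector")
}

sign_or_one <- function(x) if (x < 0) -1 else 1

#' Rotation matrix of a retardance vector
#'
#' @param rv A `retardance_vector` (list with `axis` and `angle`).
#' @return A 3x3 rotation matrix.
#' @export
retvec_to_rotation <- function(rv) {
  rot_axis_angle(rv$axis, rv$angle)
}

#' Reciprocity (D-transpose) operator
#'
#' Returns `D r^T D` with `D = diag(1, 1, -1)`, the transformation a retarder
#' undergoes on the return pass of a round-trip measurement. It is an
#' involution and leaves every linear retarder unchanged.
#'
#' @param r A 3x3 rotation matrix.
#' @return A 3x3 rotation matrix.
#' @export
d_transpose <- function(r) {
  D <- diag(c(1, 1, -1))
  D %*% t(r) %*% D
}

#' Stokes vector from detected field amplitudes
#'
#' Computes intensity and normalized Stokes components from the complex
#' horizontal and vertical field amplitudes of polarization-diverse
#' detection. Vectorized: `h` and `v` may be arrays of equal shape.
#' With this convention the field (1, i)/sqrt(2) maps to (0, 0, -1).
#'
#' @param h,v Complex field amplitudes (scalars or equal-shaped arrays).
#' @return A list with `q`, `u`, `v`, `intensity` (same shape as the inputs)
#'   and `valid` (FALSE where the intensity is zero). Components are
#'   normalized to unit norm where valid, NA elsewhere.
#' @export
stokes_from_fields <- function(h, v) {
  h <- h + 0i; v <- v + 0i
  intensity <- Mod(h)^2 + Mod(v)^2
  w <- Conj(h) * v
  valid <- intensity > 0
  I <- ifelse(valid, intensity, NA_real_)
  q <- (Mod(h)^2 - Mod(v)^2) / I
  u <- 2 * Re(w) / I
  vv <- -2 * Im(w) / I
  list(q = q, u = u, v = vv, intensity = intensity, valid = valid)
}

#' Rotation mapping one orthogonal state pair onto another
#'
#' Given two input states orthogonal on the Poincare sphere and their
#' measured counterparts, returns the unique rotation mapping the input
#' orthonormal triad `(in1, in2, in1 x in2)` onto `(out1, out2', out1 x out2')`,
#' where `out2'` is `out2` orthogonalized against `out1`.
#'
#' @param in1,in2,out1,out2 Unit Stokes 3-vectors (or `polarization_state`s).
#' @param max_dev_deg Reject (error) when either pair deviates from
#'   orthogonality by more than this many degrees.
#' @return A 3x3 rotation matrix.
#' @export
rotation_from_state_pairs <- function(in1, in2, out1, out2, max_dev_deg = 25) {
  a1 <- normalize3(state_vec(in1)); a2 <- normalize3(state_vec(in2))
  b1 <- normalize3(state_vec(out1)); b2 <- normalize3(state_vec(out2))
  dev_in <- abs(90 - acos(max(-1, min(1, sum(a1 * a2)))) * 180 / pi)
  dev_out <- abs(90 - acos(max(-1, min(1, sum(b1 * b2)))) * 180 / pi)
  if (dev_in > max_dev_deg || dev_out > max_dev_deg) {
    stop("state pairs deviate from orthogonality beyond ", max_dev_deg, " degrees")
  }
  a2 <- normalize3(a2 - sum(a1 * a2) * a1)
  b2 <- normalize3(b2 - sum(b1 * b2) * b1)
  Ain <- cbind(a1, a2, cross3(a1, a2))
  Aout <- cbind(b1, b2, cross3(b1, b2))
  Aout %*% t(Ain)
}

normalize3 <- function(x) {
  n <- sqrt(sum(x^2))
  stopifnot(n > 0)
  x / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

# circular mean of orientation angles (degrees, period 180); weights optional
circ_mean_180 <- function(theta_deg, w = NULL, na.rm = TRUE) {
  if (na.rm) {
    keep <- is.finite(theta_deg)
    theta_deg <- theta_deg[keep]
    if (!is.null(w)) w <- w[keep]
  }
  if (length(theta_deg) == 0) return(NA_real_)
  if (is.null(w)) w <- rep(1, length(theta_deg))
  a <- 2 * theta_deg * pi / 180
  m <- atan2(sum(w * sin(a)), sum(w * cos(a))) / 2 * 180 / pi
  m %% 180
}

# circular difference of orientations in degrees, wrapped to (-90, 90]
circ_diff_180 <- function(a, b) {
  d <- (a - b) %% 180
  d[d > 90] <- d[d > 90] - 180
  d
}

# circular RMSE of orientations (degrees, period 180)
circ_rmse_180 <- function(a, b, na.rm = TRUE) {
  d <- circ_diff_180(a, b)
  if (na.rm) d <- d[is.finite(d)]
  sqrt(mean(d^2))
}
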