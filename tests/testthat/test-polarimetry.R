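# Poincare-sphere algebra: retarders, logs, reciprocity, state recovery.

test_that("linear retarders match closed forms and the matrix exponential", {
  expect_equal(linear_retarder(0, 0), diag(3))
  d <- 0.7
  expect_equal(linear_retarder(0, d),
               matrix(c(1, 0, 0, 0, cos(d), sin(d), 0, -sin(d), cos(d)), 3, 3),
               tolerance = 1e-12)
  # independent oracle: exponential of the axis-angle generator
  skip_if_not_installed("Matrix")
  a <- c(0, 1, 0)  # Poincare axis of a 45-degree retarder
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  expm_ref <- as.matrix(Matrix::expm(pi * K))
  expect_equal(linear_retarder(45, pi), expm_ref, tolerance = 1e-9)
  expect_equal(linear_retarder(45, pi), diag(c(-1, 1, -1)), tolerance = 1e-9)
  set.seed(4)
  for (i in 1:5) {
    th <- runif(1, 0, 180); dd <- runif(1, 0, 3)
    a2 <- 2 * th * pi / 180
    ax <- c(cos(a2), sin(a2), 0)
    K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
    expect_equal(linear_retarder(th, dd), as.matrix(Matrix::expm(dd * K)),
                 tolerance = 1e-9)
  }
})

test_that("rotation logs round-trip and obey the documented conventions", {
  rv <- rotation_to_retvec(diag(3))
  expect_equal(rv$angle, 0)
  expect_equal(rv$axis, c(1, 0, 0))
  rv <- rotation_to_retvec(linear_retarder(30, 0.4))
  expect_equal(rv$axis, c(cos(pi / 3), sin(pi / 3), 0), tolerance = 1e-9)
  expect_equal(rv$angle, 0.4, tolerance = 1e-12)
  expect_true(rv$linear)
  # symmetry-forced pi rotation
  rv <- rotation_to_retvec(diag(c(1, -1, -1)))
  expect_equal(rv$angle, pi)
  expect_equal(rv$axis, c(1, 0, 0))
  set.seed(7)
  for (i in 1:20) {
    r <- random_rotation()
    rv <- rotation_to_retvec(r)
    expect_true(rv$angle >= 0 && rv$angle <= pi)
    expect_equal(retvec_to_rotation(rv), r, tolerance = 1e-8)
  }
  # near-pi rotations keep the round trip and the sign tie-break
  for (th in c(10, 100, 170)) {
    r <- linear_retarder(th, pi)
    rv <- rotation_to_retvec(r)
    expect_equal(retvec_to_rotation(rv), r, tolerance = 1e-7)
    expect_gt(rv$axis[which(abs(rv$axis) > 1e-9)[1]], 0)
  }
})

test_that("the reciprocity operator fixes linear retarders and reverses products", {
  expect_equal(d_transpose(diag(3)), diag(3))
  set.seed(12)
  for (i in 1:10) {
    L <- linear_retarder(runif(1, 0, 180), runif(1, 0, 3))
    expect_equal(d_transpose(L), L, tolerance = 1e-12)
    A <- random_rotation(); B <- random_rotation()
    expect_equal(d_transpose(d_transpose(A)), A, tolerance = 1e-12)
    expect_equal(d_transpose(A %*% B), d_transpose(B) %*% d_transpose(A),
                 tolerance = 1e-12)
  }
  # circular-axis rotations are reversed: dT(R_v(phi)) = R_v(-phi)
  phi <- 0.8
  Rv <- rot_axis_angle(c(0, 0, 1), phi)
  expect_equal(d_transpose(Rv), rot_axis_angle(c(0, 0, 1), -phi),
               tolerance = 1e-12)
})

test_that("round-trip products of linear retarders are D-transpose symmetric", {
  set.seed(3)
  for (i in 1:10) {
    n <- sample(2:6, 1)
    P <- diag(3)
    for (k in seq_len(n)) P <- P %*% linear_retarder(runif(1, 0, 180), runif(1, 0, 0.5))
    C <- P %*% d_transpose(P)
    expect_lt(max(abs(d_transpose(C) - C)), 1e-9)
  }
})

test_that("orientation doubling maps 90-degree rotations to antipodal axes", {
  th <- 37
  a1 <- rotation_to_retvec(linear_retarder(th, 0.5))$axis
  a2 <- rotation_to_retvec(linear_retarder(th + 90, 0.5))$axis
  expect_equal(a1, -a2, tolerance = 1e-9)
  # group closure: equal-orientation retarders compose by adding retardance
  r <- linear_retarder(th, 0.3) %*% linear_retarder(th, 0.45)
  expect_equal(r, linear_retarder(th, 0.75), tolerance = 1e-12)
})

test_that("Stokes vectors from fields follow the stated convention", {
  s <- stokes_from_fields(1, 0)
  expect_equal(c(s$q, s$u, s$v), c(1, 0, 0))
  expect_equal(s$intensity, 1)
  s <- stokes_from_fields(1 / sqrt(2), 1 / sqrt(2))
  expect_equal(c(s$q, s$u, s$v), c(0, 1, 0), tolerance = 1e-12)
  s <- stokes_from_fields(1 / sqrt(2), 1i / sqrt(2))
  expect_equal(c(s$q, s$u, s$v), c(0, 0, -1), tolerance = 1e-12)
  s <- stokes_from_fields(0, 0)
  expect_false(s$valid)
  expect_equal(s$intensity, 0)
  # unit norm wherever the intensity is positive
  set.seed(5)
  h <- complex(real = rnorm(50), imaginary = rnorm(50))
  v <- complex(real = rnorm(50), imaginary = rnorm(50))
  s <- stokes_from_fields(h, v)
  expect_equal(sqrt(s$q^2 + s$u^2 + s$v^2), rep(1, 50), tolerance = 1e-12)
})

test_that("state-pair triads recover rotations, exactly and under noise", {
  in1 <- c(1, 0, 0); in2 <- c(0, 1, 0)
  expect_equal(rotation_from_state_pairs(in1, in2, in1, in2), diag(3))
  set.seed(21)
  for (i in 1:10) {
    R <- random_rotation()
    Rhat <- rotation_from_state_pairs(in1, in2, R %*% in1, R %*% in2)
    expect_equal(Rhat, R, tolerance = 1e-9)
    expect_lt(max(abs(Rhat %*% in1 - R %*% in1)), 1e-6)
  }
  # Monte-Carlo: sigma = 0.01 per component, renormalized, 100 draws
  set.seed(22)
  errs <- replicate(100, {
    R <- random_rotation()
    noisy <- function(x) {
      y <- x + rnorm(3, 0, 0.01)
      y / sqrt(sum(y^2))
    }
    Rhat <- rotation_from_state_pairs(in1, in2, noisy(R %*% in1), noisy(R %*% in2))
    rotation_to_retvec(Rhat %*% t(R))$angle * 180 / pi
  })
  expect_lt(mean(errs), 1)
  # far-from-orthogonal pairs are rejected
  expect_error(rotation_from_state_pairs(in1, c(0.9, 0.1, 0) / sqrt(0.82),
                                         in1, in2),
               "orthogonality")
})
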