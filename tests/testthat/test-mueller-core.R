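test_that("ideal polariser generator matches canonical matrices and is idempotent", {
  expect_matrix_equal(
    linear_polariser_mueller(0),
    0.5 * matrix(c(1, 1, 0, 0, 1, 1, 0, 0, rep(0, 8)), 4, 4, byrow = TRUE))
  expect_matrix_equal(
    linear_polariser_mueller(45),
    0.5 * matrix(c(1, 0, 1, 0, 0, 0, 0, 0, 1, 0, 1, 0, 0, 0, 0, 0),
                 4, 4, byrow = TRUE))
  for (th in c(0, 17, 30, 45, 90, 135, 161)) {
    m <- linear_polariser_mueller(th)
    # with unit maximum transmittance the polariser is a projection: M^2 = M
    expect_matrix_equal(m %*% m, m)
    expect_equal(m[1, 4], 0)
    expect_equal(m[4, 1], 0)
  }
})

test_that("ideal retarder is non-absorbing with an orthogonal polarisation block", {
  expect_matrix_equal(linear_retarder_mueller(72, 0), diag(4))
  for (th in c(0, 22.5, 45, 80, 90, 135)) {
    for (de in c(10, 60, 90, 97.2, 170)) {
      m <- linear_retarder_mueller(th, de)
      expect_equal(m[1, 1], 1)
      block <- m[2:4, 2:4]
      expect_matrix_equal(crossprod(block), diag(3))
      expect_equal(det(block), 1, tolerance = 1e-12)
    }
  }
})

test_that("mirror is the helicity-flipping involution", {
  m <- mirror_mueller()
  expect_equal(m, diag(c(1, 1, -1, -1)))
  expect_equal(linear_submatrix(m)[3, 3], -1)
  expect_matrix_equal(m %*% m, diag(4))
  expect_equal(apply_mueller(m, c(1, 0, 1, 0)), c(1, 0, -1, 0))
})

test_that("double pass composes in 4x4 with the 180 - theta second pass", {
  # polariser at 45: half-transmittance pattern with the U-row sign flip
  dp45 <- linear_submatrix(double_pass("polariser", 45))
  expect_matrix_equal(dp45, 0.5 * matrix(c(1, 0, 1, 0, 0, 0, -1, 0, -1),
                                         3, 3, byrow = TRUE))
  expect_equal(dp45[1, 1], 0.5)
  # polariser at 0
  expect_matrix_equal(
    linear_submatrix(double_pass("polariser", 0)),
    0.5 * matrix(c(1, 1, 0, 1, 1, 0, 0, 0, 0), 3, 3, byrow = TRUE))
  # quarter-wave-like retarder at 0.27 wavelengths
  qwp <- linear_submatrix(double_pass("retarder", 45, 97.2))
  expect_matrix_equal(qwp, diag(c(1, cos(194.4 * pi / 180), -1)))
  expect_equal(round(qwp[2, 2], 2), -0.97)
  # vertical-axis 30 degree retarder
  expect_matrix_equal(linear_submatrix(double_pass("retarder", 90, 30)),
                      diag(c(1, 1, -0.5)))
  expect_error(double_pass("retarder", 45), "delta")
  expect_error(double_pass("polariser", 45, delta = 30), "delta")
})

test_that("retarder double pass matches the closed form on a delta grid", {
  for (de in seq(0, 180, by = 7.5)) {
    got <- linear_submatrix(double_pass("retarder", 45, de))
    want <- diag(c(1, cos(2 * de * pi / 180), -1))
    expect_matrix_equal(got, want)
  }
})

test_that("pass-by-pass 3x3 composition is wrong for retarders", {
  # Composing linear submatrices loses the linear<->circular coupling: the
  # (2,2) element comes out cos^2(delta) instead of the correct cos(2 delta).
  de <- 60
  a3 <- linear_submatrix(linear_retarder_mueller(45, de))
  b3 <- linear_submatrix(linear_retarder_mueller(135, de))
  wrong <- b3 %*% diag(c(1, 1, -1)) %*% a3
  right <- linear_submatrix(double_pass("retarder", 45, de))
  expect_equal(wrong[2, 2], cos(de * pi / 180)^2, tolerance = 1e-12)
  expect_equal(right[2, 2], cos(2 * de * pi / 180), tolerance = 1e-12)
  expect_gt(abs(wrong[2, 2] - right[2, 2]), 0.7)
})

test_that("applying generated elements never raises the degree of polarisation", {
  set.seed(101)
  for (i in 1:40) {
    s <- stokes_linear_state(stats::runif(1, 0, 180),
                             dop = stats::runif(1),
                             intensity = stats::runif(1, 0.1, 5))
    m <- switch(sample(3, 1),
                linear_polariser_mueller(stats::runif(1, 0, 180)),
                linear_retarder_mueller(stats::runif(1, 0, 180),
                                        stats::runif(1, 0, 360)),
                double_pass("retarder", stats::runif(1, 0, 180),
                            stats::runif(1, 0, 360)))
    out <- apply_mueller(m, s)
    if (out[1] > 1e-9) expect_lte(stokes_dop(out), 1 + 1e-12)
  }
})

test_that("apply_mueller enforces dimension agreement", {
  expect_equal(apply_mueller(diag(4), c(1, 0.2, 0.3, 0)), c(1, 0.2, 0.3, 0))
  expect_equal(apply_mueller(linear_polariser_mueller(0), c(1, 0, 0, 0)),
               c(0.5, 0.5, 0, 0))
  expect_error(apply_mueller(diag(3), c(1, 0, 0, 0)), "length 3")
})

test_that("sample-frame rotation shifts a retarder axis by the rotation angle", {
  m <- linear_submatrix(linear_retarder_mueller(20, 70))
  expect_matrix_equal(rotate_sample_frame(m, 0), m)
  expect_matrix_equal(rotate_sample_frame(m, 180), m)
  for (phi in c(10, 33, 90, 120)) {
    expect_matrix_equal(
      rotate_sample_frame(m, phi),
      linear_submatrix(linear_retarder_mueller(20 + phi, 70)))
  }
})

test_that("linear Stokes states carry the requested polarisation", {
  expect_equal(stokes_linear_state(0), c(1, 1, 0, 0))
  expect_equal(stokes_linear_state(-45), c(1, 0, -1, 0), tolerance = 1e-15)
  s <- stokes_linear_state(20, dop = 0.15)
  expect_equal(stokes_dop(s), 0.15)
  expect_error(stokes_linear_state(0, dop = 1.2), "dop")
  expect_error(stokes_linear_state(0, intensity = -1), "intensity")
  expect_equal(canonical_axis(-45), 135)
  expect_equal(canonical_axis(180), 0)
})
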