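test_that("rotations are proper and agree with known cases", {
  set.seed(11)
  for (i in 1:25) {
    ax <- rnorm(3)
    ang <- runif(1, -pi, pi)
    R <- htosim:::rotation_about_axis(ax, ang)
    expect_true(htosim:::is_proper_rotation(R))
    # axis is fixed
    expect_vec_equal(R %*% htosim:::unitv(ax), htosim:::unitv(ax), 1e-12)
  }
  Rz90 <- htosim:::rotation_about_axis(c(0, 0, 1), pi / 2)
  expect_vec_equal(Rz90 %*% c(1, 0, 0), c(0, 1, 0), 1e-12)
})

test_that("rigid transforms fix their pivot and preserve distances", {
  set.seed(12)
  for (i in 1:20) {
    pivot <- rnorm(3, sd = 50)
    tf <- htosim:::rigid_about_point(
      htosim:::rotation_about_axis(rnorm(3), runif(1, -pi, pi)), pivot)
    expect_vec_equal(htosim:::apply_rigid(tf, pivot), pivot, 1e-9)
    a <- rnorm(3, sd = 100); b <- rnorm(3, sd = 100)
    d0 <- htosim:::vnorm(a - b)
    d1 <- htosim:::vnorm(htosim:::apply_rigid(tf, a) - htosim:::apply_rigid(tf, b))
    expect_lt(abs(d1 - d0), 1e-9)
    # matrix and vector application agree
    m <- rbind(a, b)
    mm <- htosim:::apply_rigid(tf, m)
    expect_vec_equal(mm[1, ], htosim:::apply_rigid(tf, a), 1e-12)
  }
})

test_that("plane and line distances behave", {
  expect_equal(htosim:::plane_signed_distance(c(0, 0, 3), c(0, 0, 1), c(0, 0, 2)), 2)
  expect_equal(htosim:::point_line_distance(c(3, 4, 0), c(0, 0, 0), c(0, 0, 1)), 5)
  m <- rbind(c(0, 0, 3), c(0, 0, -1))
  expect_equal(htosim:::plane_signed_distance(m, c(0, 0, 1), c(0, 0, 1)), c(2, -2))
})
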