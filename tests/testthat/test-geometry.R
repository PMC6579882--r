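test_that("t-map thresholding matches the one-sided critical value", {
  tm <- array(0, c(4, 4, 4))
  expect_equal(sum(threshold_tmap(tm, dof = 20)), 0)
  tm[1, 1, 1] <- 10
  expect_true(threshold_tmap(tm, dof = 30)[1, 1, 1])
  crit <- qt(0.95, df = 12)
  tm2 <- array(c(crit + 1e-6, crit - 1e-6, rep(0, 62)), c(4, 4, 4))
  mask <- threshold_tmap(tm2, dof = 12, alpha = 0.05)
  expect_true(mask[1, 1, 1])
  expect_false(mask[2, 1, 1])
})

test_that("center of mass is the mean world coordinate", {
  aff <- diag(c(2, 2, 2, 1)); aff[1:3, 4] <- c(10, -20, 5)
  m <- array(FALSE, c(5, 5, 5))
  m[1, 1, 1] <- TRUE  # voxel (0,0,0) -> world (10, -20, 5)
  expect_equal(center_of_mass(m, aff), c(10, -20, 5))
  aff0 <- diag(4); aff0[1:3, 4] <- c(-2, -2, -2)
  m2 <- array(FALSE, c(5, 5, 5))
  m2[1, 1, 1] <- TRUE; m2[5, 5, 5] <- TRUE  # symmetric about the origin
  expect_equal(center_of_mass(m2, aff0), c(0, 0, 0))
  m3 <- array(FALSE, c(5, 5, 5))
  m3[2:3, 2:3, 2:3] <- TRUE  # 2x2x2 block: centroid of the 8 corners
  expect_equal(center_of_mass(m3, diag(4)), c(1.5, 1.5, 1.5))
  expect_warning(com <- center_of_mass(array(FALSE, c(3, 3, 3))), "empty")
  expect_true(all(is.nan(com)))
})

test_that("activation maxima use deterministic tie-breaking", {
  tm <- array(0, c(4, 4, 4))
  roi <- array(TRUE, c(4, 4, 4))
  tm[3, 2, 1] <- 5
  expect_equal(activation_maximum(tm, roi, diag(4)), c(2, 1, 0))
  tm[1, 1, 2] <- 5  # equal peak at a higher linear index? (1,1,2) is later
  expect_equal(activation_maximum(tm, roi, diag(4)), c(2, 1, 0))
  expect_equal(activation_maximum(tm + 3, roi, diag(4)), c(2, 1, 0))
  expect_error(activation_maximum(tm, array(FALSE, c(4, 4, 4))), "empty")
})

test_that("adjusted volume is the ROI-normalized overlap", {
  roi <- array(FALSE, c(4, 4, 4)); roi[1:2, 1:2, 1:2] <- TRUE
  expect_equal(adjusted_volume(roi, roi), 1)
  half <- array(FALSE, c(4, 4, 4)); half[1, 1:2, 1:2] <- TRUE
  expect_equal(adjusted_volume(half, roi), 0.5)
  expect_equal(adjusted_volume(!roi, roi), 0)
})

test_that("betweenness uses strict per-axis ordering", {
  b <- betweenness_check(c(0, 0, 10), c(0, 0, 5), c(0, 0, 0))
  expect_true(b$per_axis[["Z"]])
  expect_true(b$any_axis)
  expect_false(betweenness_check(c(0, 0, 10), c(0, 0, 11), c(0, 0, 0))$any_axis)
  expect_false(betweenness_check(c(0, 0, 10), c(0, 0, 10), c(0, 0, 0))$any_axis)
  expect_true(is.na(betweenness_check(c(0, 0, NaN), c(0, 0, 5),
                                      c(0, 0, 0))$any_axis))
})

test_that("direction checks follow the per-structure expectation table", {
  expect_true(direction_check(list(foot = c(0, 0, 10), face = c(0, 0, 2)),
                              "putamen_L"))
  expect_false(direction_check(list(foot = c(0, 0, 2), face = c(0, 0, 10)),
                               "putamen_L"))
  # thalamus: lateral-to-medial gradient evaluated on |X|
  expect_true(direction_check(list(foot = c(-20, 0, 0), face = c(-10, 0, 0)),
                              "thalamus_L"))
  expect_false(direction_check(list(foot = c(-10, 0, 0), face = c(-20, 0, 0)),
                               "thalamus_L"))
  expect_false(direction_check(list(foot = c(0, 0, 5), face = c(0, 0, 5)),
                               "putamen_R"))
  expect_error(direction_check(list(foot = c(0, 0, 1), face = c(0, 0, 0)),
                               "cerebellum_L"), "expectation")
})

test_that("principal-axis projection recovers a linear arrangement", {
  t_axis <- c(1, 1, 0) / sqrt(2)
  pts <- outer(seq(-2, 2), t_axis)
  pr <- principal_axis_projection(pts)
  expect_equal(abs(sum(pr$axes[, 1] * t_axis)), 1, tolerance = 1e-10)
  expect_equal(pr$singular_values[2:3], c(0, 0), tolerance = 1e-10)
  expect_error(principal_axis_projection(matrix(1, 4, 3)), "distinct")
})

test_that("projection is an isometry and rotation equivariant up to sign", {
  set.seed(20)
  pts <- matrix(rnorm(27), 9, 3)
  pr <- principal_axis_projection(pts)
  expect_equal(as.matrix(dist(pr$projected)), as.matrix(dist(pts)),
               tolerance = 1e-10)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  pr2 <- principal_axis_projection(pts %*% t(R))
  for (j in 1:3)
    expect_equal(abs(pr2$projected[, j]), abs(pr$projected[, j]),
                 tolerance = 1e-8)
})

test_that("suprathreshold volume is monotone in the threshold", {
  set.seed(21)
  tm <- array(rnorm(1000, mean = 1), c(10, 10, 10))
  roi <- array(TRUE, c(10, 10, 10))
  alphas <- c(0.2, 0.1, 0.05, 0.01)
  vols <- sapply(alphas, function(a)
    adjusted_volume(threshold_tmap(tm, dof = 15, alpha = a), roi))
  expect_true(all(diff(vols) <= 0))
})
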