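test_that("rigid matrix construction matches the explicit factor product", {
  expect_equal(build_rigid_matrix(rep(0, 6)), diag(4))
  M <- build_rigid_matrix(c(5, 0, 0, 0, 0, 0))
  expect_equal(M, {
    E <- diag(4); E[1, 4] <- 5; E
  })
  # explicit numeric product of the four factor matrices as oracle
  p <- c(1, 2, 3, 0.1, 0.2, 0.3)
  Tm <- diag(4); Tm[1:3, 4] <- p[1:3]
  rx <- diag(4); rx[2:3, 2:3] <- matrix(c(cos(p[4]), sin(p[4]),
                                          -sin(p[4]), cos(p[4])), 2)
  ry <- diag(4); ry[c(1, 3), c(1, 3)] <- matrix(c(cos(p[5]), -sin(p[5]),
                                                  sin(p[5]), cos(p[5])), 2)
  rz <- diag(4); rz[1:2, 1:2] <- matrix(c(cos(p[6]), sin(p[6]),
                                          -sin(p[6]), cos(p[6])), 2)
  expect_equal(build_rigid_matrix(p), Tm %*% rx %*% ry %*% rz,
               tolerance = 1e-12)
  expect_error(build_rigid_matrix(c(1, 2, 3, NA, 0, 0)), "finite")
})

test_that("rotation blocks are orthonormal with det +1 for random params", {
  set.seed(42)
  for (i in 1:25) {
    p <- c(runif(3, -20, 20), runif(3, -pi, pi))
    R <- build_rigid_matrix(p)[1:3, 1:3]
    expect_lt(max(abs(t(R) %*% R - diag(3))), 1e-10)
    expect_equal(det(R), 1, tolerance = 1e-10)
  }
})

test_that("decompose_rigid inverts build_rigid_matrix away from gimbal lock", {
  expect_equal(unname(decompose_rigid(diag(4))), rep(0, 6))
  set.seed(7)
  for (i in 1:20) {
    p <- c(runif(3, -30, 30), runif(2, -pi, pi), runif(1, -1.4, 1.4))
    p <- p[c(1, 2, 3, 4, 6, 5)]  # keep p5 away from +/- pi/2
    M <- build_rigid_matrix(p)
    expect_equal(unname(decompose_rigid(M)), p, tolerance = 1e-8)
    expect_lt(max(abs(build_rigid_matrix(decompose_rigid(M)) - M)), 1e-8)
  }
  S <- diag(c(2, 2, 2, 1))
  expect_error(decompose_rigid(S), "not rigid")
  expect_error(decompose_rigid(build_rigid_matrix(c(0, 0, 0, 0.3, pi / 2, 0.2))),
               "gimbal")
})

test_that("inter-image composition bridges through the template", {
  set.seed(11)
  M1 <- build_rigid_matrix(c(runif(3, -5, 5), runif(3, -0.3, 0.3)))
  M2 <- build_rigid_matrix(c(runif(3, -5, 5), runif(3, -0.3, 0.3)))
  expect_equal(compose_inter_image_transform(M1, M1), diag(4),
               tolerance = 1e-12)
  expect_equal(compose_inter_image_transform(diag(4), M2), solve(M2),
               tolerance = 1e-12)
  # brute-force product with explicitly inverted M2
  expect_equal(compose_inter_image_transform(M1, M2), solve(M2) %*% M1,
               tolerance = 1e-12)
  # the composed transform actually carries image-1 points onto image-2
  # points when both registrations share a template-space target
  x1 <- c(3, -2, 7, 1)
  xt <- M1 %*% x1                         # template-space position
  x2 <- solve(M2) %*% xt                  # image-2 position of the same point
  expect_equal(compose_inter_image_transform(M1, M2) %*% x1, x2,
               tolerance = 1e-12)
  expect_error(compose_inter_image_transform(M1, matrix(0, 4, 4)), "singular")
})

test_that("resampling: identity restore, integer shifts, rotation round-trip", {
  v <- ball_volume(c(16, 16, 16), radius = 5)
  m <- brain_volume((v$data > 50) + 0, v$spacing, v$affine)
  expect_identical(resample(m, diag(4), m, mode = "nearest")$data, m$data)

  # integer-voxel translation permutes the grid
  M <- build_rigid_matrix(c(2, 0, 0, 0, 0, 0))
  sh <- resample(m, M, m, mode = "nearest")$data
  expect_identical(sort(unique(as.numeric(sh))), c(0, 1))
  expect_identical(sh[4:16, , ], m$data[2:14, , ])

  # rotate 30 deg and back, linear mode: small interpolation loss only
  R <- build_rigid_matrix(c(0, 0, 0, 0, 0, pi / 6))
  there <- resample(v, R, v, mode = "linear")
  back <- resample(there, solve(R), v, mode = "linear")
  interior <- ball_volume(c(16, 16, 16), radius = 7)$data > 50
  mae <- mean(abs(back$data - v$data)[interior])
  expect_lt(mae, 8)  # a few percent of the 100-unit edge height
})

test_that("trilinear resampling agrees with a pointwise interpolation oracle", {
  set.seed(5)
  a <- array(rnorm(12 * 12 * 12), c(12, 12, 12))
  v <- brain_volume(a, spacing = c(1, 1, 1),
                    affine = diag(4))  # voxel == world coordinates
  M <- build_rigid_matrix(c(0.3, -0.7, 0.2, 0.05, -0.04, 0.08))
  out <- resample(v, M, v, mode = "linear")
  Minv <- solve(M)
  for (i in 1:20) {
    ix <- sample(3:10, 3)
    src <- (Minv %*% c(ix, 1))[1:3]
    expect_equal(out$data[ix[1] + 1, ix[2] + 1, ix[3] + 1],
                 brute_trilinear(a, src), tolerance = 1e-6,
                 label = paste("voxel", paste(ix, collapse = ",")))
  }
})
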