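make_prob <- function(p, dm, spacing = c(1, 1, 1)) {
  structure(list(p = p, dim = dm, spacing = spacing,
                 affine = diag(c(spacing, 1))), class = "tissue_prob")
}

test_that("prior mapping is the identity on a shared grid and shifts with M", {
  cfg <- tiny_config()
  tp <- generate_template(cfg)
  target <- brain_volume(array(0, cfg$shape), cfg$spacing,
                         tp$priors$affine)
  p0 <- map_priors(tp$priors, diag(4), target)
  expect_equal(array(p0$p, c(cfg$shape, 4)), unname(tp$priors$p),
               tolerance = 1e-9)

  # integer-voxel translation shifts the priors: M carries image voxels
  # +2 mm along x in template space, so the sampled prior moves by +2
  M <- build_rigid_matrix(c(2, 0, 0, 0, 0, 0))
  p1 <- map_priors(tp$priors, M, target)
  a0 <- array(p0$p[, 1], cfg$shape)
  a1 <- array(p1$p[, 1], cfg$shape)
  expect_equal(a1[1:30, , ], a0[3:32, , ], tolerance = 1e-9)
})

test_that("prior mapping matches a pointwise interpolation oracle", {
  set.seed(8)
  dm <- c(10, 10, 10)
  smooth <- array(0, c(dm, 4))
  base <- array(runif(prod(dm)), dm)
  smooth[, , , 1] <- base
  smooth[, , , 4] <- 1 - base
  pri <- tissue_priors(smooth, spacing = c(1, 1, 1), affine = diag(4))
  target <- brain_volume(array(0, dm), c(1, 1, 1), diag(4))
  M <- build_rigid_matrix(c(0.4, -0.3, 0.6, 0.03, 0.02, -0.05))
  mp <- map_priors(pri, M, target)
  for (i in 1:20) {
    ix <- sample(3:8, 3)
    n <- ix[1] + 1 + dm[1] * ix[2] + dm[1] * dm[2] * ix[3]
    src <- (M %*% c(ix, 1))[1:3]   # template-space position of image voxel
    raw <- c(brute_trilinear(pri$p[, , , 1], src), 0, 0,
             brute_trilinear(pri$p[, , , 4], src))
    expect_equal(unname(mp$p[n, 1]), raw[1] / sum(raw), tolerance = 1e-6)
  }
})

test_that("cluster statistics match a naive per-voxel loop", {
  set.seed(12)
  n <- 500
  p <- matrix(runif(n * 4), n, 4); p <- p / rowSums(p)
  f <- rnorm(n, 50, 20)
  st <- update_cluster_stats(p, f, sigma_floor = 1e-12, mass_floor = 0)
  for (k in 1:4) {
    mk <- 0; muk <- 0
    for (i in 1:n) { mk <- mk + p[i, k]; muk <- muk + p[i, k] * f[i] }
    muk <- muk / mk
    sk <- 0
    for (i in 1:n) sk <- sk + p[i, k] * (f[i] - muk)^2
    sk <- sk / mk
    expect_equal(unname(st$m[k]), mk, tolerance = 1e-9)
    expect_equal(unname(st$mu[k]), muk, tolerance = 1e-9)
    expect_equal(unname(st$sigma[k]), sk, tolerance = 1e-9)
  }
  expect_equal(sum(st$m), n, tolerance = 1e-3)
})

test_that("cluster statistics handle concentrated and split memberships", {
  n <- 100
  p <- cbind(rep(1, n), 0, 0, 0)
  st <- update_cluster_stats(p, rep(7, n), sigma_floor = 1e-4)
  expect_equal(unname(st$mu[1]), 7)
  expect_equal(unname(st$sigma[1]), 1e-4)  # floored
  expect_equal(unname(st$m[1]), n)

  p <- matrix(0, n, 4); p[1:50, 1] <- 1; p[51:100, 2] <- 1
  f <- c(rep(0, 50), rep(10, 50))
  st <- update_cluster_stats(p, f, mass_floor = 0)
  expect_equal(unname(st$mu[1:2]), c(0, 10))
  expect_equal(unname(st$m[1:2]), c(50, 50))
  expect_error(update_cluster_stats(matrix(0, n, 4), f), "all-zero")
})

test_that("gaussian density uses the variance parameterisation", {
  expect_equal(gaussian_density(0, 0, 1 / (2 * pi)), 1)
  expect_equal(gaussian_density(2, 0, 4), gaussian_density(0, 0, 4) * exp(-1 / 2))
  # integrates to one
  x <- seq(-30, 30, by = 0.01)
  expect_equal(sum(gaussian_density(x, 0, 4)) * 0.01, 1, tolerance = 1e-4)
  expect_error(gaussian_density(0, 0, 0), "> 0")
})

test_that("EM recovers a well-separated two-class mixture with priors", {
  set.seed(21)
  dm <- c(12, 12, 12)
  n <- prod(dm)
  truth <- array(rep(c(0, 1), length.out = n), dm)
  f <- ifelse(truth == 1, rnorm(n, 70, 2), rnorm(n, 30, 2))
  img <- brain_volume(array(f, dm))
  # informative but soft priors over the two active classes
  p <- matrix(0, n, 4)
  p[, 1] <- ifelse(truth == 0, 0.7, 0.3)
  p[, 2] <- 1 - p[, 1]
  seg <- em_segment(img, make_prob(p, dm),
                    cfg = segmentation_settings(max_iter = 60))
  expect_equal(unname(seg$stats$mu[1]), 30, tolerance = 1)
  expect_equal(unname(seg$stats$mu[2]), 70, tolerance = 1)
  hard <- max.col(seg$probabilities$p)
  expect_gte(mean(hard == (as.numeric(truth) + 1)), 0.99)
})

test_that("one-hot priors on separated classes are a fixed point", {
  set.seed(22)
  dm <- c(10, 10, 10)
  n <- prod(dm)
  truth <- rep(1:2, length.out = n)
  f <- ifelse(truth == 1, rnorm(n, 20, 1), rnorm(n, 80, 1))
  p <- matrix(0, n, 4); p[cbind(1:n, truth)] <- 1
  seg <- em_segment(brain_volume(array(f, dm)), make_prob(p, dm))
  expect_lt(max(abs(seg$probabilities$p - p)), 1e-3)
})

test_that("probabilities stay normalised and deltas stabilise", {
  cfg <- tiny_config(seed = 6)
  tp <- generate_template(cfg)
  tr <- generate_subject(cfg, 5)
  vis <- generate_visit(tr, 13, motion = rep(0, 6), gain = 1)
  seg <- em_segment(vis$volume, tp$priors, diag(4),
                    segmentation_settings(tol = 1e-12, max_iter = 10))
  expect_lt(max(abs(rowSums(seg$probabilities$p) - 1)), 1e-6)
  expect_true(all(seg$probabilities$p >= 0 & seg$probabilities$p <= 1))
  # per-iteration mass conservation
  n <- prod(cfg$shape)
  for (st in seg$stats_trace)
    expect_equal(unname(sum(st$m)), n, tolerance = 1e-3 * n)
  # monotone stabilisation: late deltas sit below those 3 iterations earlier
  d <- seg$delta_trace
  if (length(d) >= 7) {
    late <- (length(d) - 2):length(d)
    expect_true(all(d[late] < d[late - 3]))
  }
})

test_that("flat priors reduce to plain Gaussian-mixture EM", {
  skip_if_not_installed("mclust")
  suppressPackageStartupMessages(library(mclust))
  set.seed(30)
  dm <- c(12, 12, 12)
  n <- prod(dm)
  f <- c(rnorm(n / 2, 30, 2), rnorm(n / 2, 70, 2))[sample(n)]
  # flat weights over two active clusters, jittered to break the exactly
  # symmetric fixed point (as any mixture EM initialisation must)
  e <- runif(n, -0.05, 0.05)
  p <- cbind(0.5 + e, 0.5 - e, 0, 0)
  seg <- em_segment(brain_volume(array(f, dm)), make_prob(p, dm),
                    cfg = segmentation_settings(prior_mode = "initial",
                                                tol = 1e-7, max_iter = 200))
  ref <- mclust::Mclust(f, G = 2, modelNames = "V", verbose = FALSE)
  mu_ref <- sort(ref$parameters$mean)
  close <- vapply(mu_ref, function(m) min(abs(seg$stats$mu[1:2] - m)) / m, 1)
  expect_lt(max(close), 0.01)
})

test_that("degenerate constant images are flagged, not fatal", {
  dm <- c(8, 8, 8)
  p <- matrix(0.25, prod(dm), 4)
  seg <- em_segment(brain_volume(array(5, dm)), make_prob(p, dm))
  expect_false(seg$converged)
  expect_identical(seg$n_iter, 0L)
})
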