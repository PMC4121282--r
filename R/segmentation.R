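#' Map template tissue priors into an image's space
#'
#' Initial per-voxel class probabilities are obtained by sampling each prior
#' class at the template-space position of every image voxel (trilinear
#' interpolation) and renormalising the four classes to sum to one. Voxels
#' whose template-space position falls outside the prior field of view get
#' probability 1 for the "other" class.
#'
#' @param priors a [tissue_priors] set living in template space.
#' @param M 4x4 rigid matrix mapping the image's world space onto template
#'   space (the output of [estimate_rigid()]).
#' @param target a [brain_volume] supplying the image grid.
#' @return An object of class `tissue_prob`: `p` (N x 4 matrix, columns GM,
#'   WM, CSF, other), `dim`, `spacing`, `affine`.
#' @export
map_priors <- function(priors, M, target) {
  stopifnot(inherits(priors, "tissue_priors"), inherits(target, "brain_volume"))
  M <- as.matrix(M)
  if (abs(det(M)) < 1e-12) stop("transform is singular")
  dm <- dim(target$data)
  n <- prod(dm)
  p <- matrix(0, n, 4L, dimnames = list(NULL, TISSUE_CLASSES))
  # priors live in template space; image voxel -> template world via M
  for (k in 1:4) {
    pk <- prior_volume(priors, k)
    p[, k] <- resample(pk, solve(M), target, mode = "linear")$data
  }
  tot <- rowSums(p)
  outside <- tot < 1e-6
  p[outside, ] <- rep(c(0, 0, 0, 1), each = sum(outside))
  tot[outside] <- 1
  p <- p / tot
  structure(list(p = p, dim = dm, spacing = target$spacing,
                 affine = target$affine),
            class = "tissue_prob")
}

#' Per-cluster weighted statistics
#'
#' Given the current membership probabilities, computes for each class the
#' effective voxel count `m_k = sum_n p_nk`, the probability-weighted mean
#' intensity and the probability-weighted variance. Variances are floored at
#' `sigma_floor`; clusters with mass below `mass_floor` keep the previous
#' statistics (if supplied) and are flagged.
#'
#' @param p N x 4 probability matrix (or a `tissue_prob`).
#' @param image a [brain_volume] (or numeric vector of N intensities).
#' @param sigma_floor minimum variance; defaults to
#'   `1e-4 * diff(range(image))^2`.
#' @param mass_floor minimum effective voxel count for a cluster update.
#' @param prev previous statistics to retain for starved clusters.
#' @return A list with `m`, `mu`, `sigma` (length-4, named) and `flagged`
#'   (logical, clusters whose update was skipped).
#' @export
update_cluster_stats <- function(p, image, sigma_floor = NULL,
                                 mass_floor = 10, prev = NULL) {
  if (inherits(p, "tissue_prob")) p <- p$p
  f <- if (inherits(image, "brain_volume")) as.numeric(image$data) else as.numeric(image)
  stopifnot(is.matrix(p), ncol(p) == 4L, nrow(p) == length(f))
  if (all(p == 0)) stop("all-zero probability field")
  if (is.null(sigma_floor)) {
    rng <- diff(range(f))
    sigma_floor <- max(1e-4 * rng^2, 1e-12)
  }
  m <- colSums(p)
  mu <- as.numeric(crossprod(p, f)) / pmax(m, .Machine$double.eps)
  sig <- numeric(4)
  for (k in 1:4) sig[k] <- sum(p[, k] * (f - mu[k])^2) / max(m[k], .Machine$double.eps)
  sig <- pmax(sig, sigma_floor)
  flagged <- m < mass_floor
  if (any(flagged) && !is.null(prev)) {
    mu[flagged] <- prev$mu[flagged]
    sig[flagged] <- prev$sigma[flagged]
  }
  names(m) <- names(mu) <- names(sig) <- TISSUE_CLASSES
  list(m = m, mu = mu, sigma = sig, flagged = flagged)
}

#' Gaussian probability density with variance parameterisation
#'
#' `(2 pi sigma)^(-1/2) exp(-(f - mu)^2 / (2 sigma))`, where `sigma` is the
#' cluster *variance* (the same quantity produced by
#' [update_cluster_stats()]).
#'
#' @param f intensity value(s).
#' @param mu cluster mean intensity.
#' @param sigma cluster intensity variance, > 0.
#' @return Density value(s).
#' @export
gaussian_density <- function(f, mu, sigma) {
  if (any(sigma <= 0)) stop("sigma (variance) must be > 0")
  exp(-(f - mu)^2 / (2 * sigma)) / sqrt(2 * pi * sigma)
}

#' Segmentation settings
#'
#' @param tol convergence tolerance on the mean absolute per-voxel
#'   probability change between iterations.
#' @param max_iter maximum number of iterations.
#' @param sigma_floor,mass_floor degeneracy guards, see
#'   [update_cluster_stats()].
#' @param prior_mode `"current"` multiplies the class densities by the
#'   probabilities of the previous iteration (the printed update);
#'   `"initial"` multiplies by the fixed initial priors, which with flat
#'   priors reduces the scheme to plain Gaussian-mixture EM responsibilities.
#' @return Settings list for [em_segment()].
#' @export
segmentation_settings <- function(tol = 1e-4, max_iter = 30L,
                                  sigma_floor = NULL, mass_floor = 10,
                                  prior_mode = c("current", "initial")) {
  stopifnot(tol > 0, max_iter >= 1)
  list(tol = tol, max_iter = as.integer(max_iter),
       sigma_floor = sigma_floor, mass_floor = mass_floor,
       prior_mode = match.arg(prior_mode))
}

#' Prior-initialised mixture-model tissue classification
#'
#' Iterative maximum-likelihood classification of voxel intensities into
#' GM/WM/CSF/other. Membership probabilities are initialised by mapping the
#' template priors through the rigid transform; each iteration recomputes
#' the cluster masses, means and variances from the current probabilities,
#' evaluates the Gaussian class densities at every voxel, multiplies them by
#' the per-voxel prior weights and renormalises so classes sum to one per
#' voxel. Iteration stops when the mean absolute probability change drops
#' below `cfg$tol` or `cfg$max_iter` is reached.
#'
#' @param image [brain_volume] to segment.
#' @param priors [tissue_priors] in template space (or a precomputed
#'   `tissue_prob` already on the image grid).
#' @param M rigid image-to-template matrix (ignored when `priors` is a
#'   `tissue_prob`).
#' @param cfg settings from [segmentation_settings()].
#' @return An object of class `segmentation_result`: `probabilities`
#'   (`tissue_prob`), `stats` (final cluster statistics), `stats_trace`
#'   (per-iteration statistics), `n_iter`, `converged`, `delta_trace`.
#' @export
em_segment <- function(image, priors, M = diag(4),
                       cfg = segmentation_settings()) {
  stopifnot(inherits(image, "brain_volume"))
  f <- as.numeric(image$data)
  if (diff(range(f)) == 0) {
    # constant image: no intensity information, flag and return priors as-is
    p0 <- if (inherits(priors, "tissue_prob")) priors else map_priors(priors, M, image)
    return(structure(list(probabilities = p0, stats = NULL,
                          stats_trace = list(), n_iter = 0L,
                          converged = FALSE, delta_trace = numeric(0)),
                     class = "segmentation_result"))
  }
  p0 <- if (inherits(priors, "tissue_prob")) priors else map_priors(priors, M, image)
  p <- p0$p
  pinit <- p
  sigma_floor <- cfg$sigma_floor
  if (is.null(sigma_floor)) sigma_floor <- max(1e-4 * diff(range(f))^2, 1e-12)
  stats <- NULL
  stats_trace <- list()
  delta_trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  while (iter < cfg$max_iter) {
    iter <- iter + 1L
    stats <- update_cluster_stats(p, f, sigma_floor = sigma_floor,
                                  mass_floor = cfg$mass_floor, prev = stats)
    stats_trace[[iter]] <- stats
    q <- matrix(0, nrow(p), 4L)
    w <- if (cfg$prior_mode == "initial") pinit else p
    for (k in 1:4)
      q[, k] <- gaussian_density(f, stats$mu[k], stats$sigma[k]) * w[, k]
    tot <- rowSums(q)
    bad <- tot <= .Machine$double.xmin
    if (any(bad)) { q[bad, ] <- 0.25; tot[bad] <- 1 }
    pn <- q / tot
    delta <- mean(abs(pn - p))
    delta_trace <- c(delta_trace, delta)
    p <- pn
    if (delta < cfg$tol) { converged <- TRUE; break }
  }
  colnames(p) <- TISSUE_CLASSES
  probs <- structure(list(p = p, dim = p0$dim, spacing = p0$spacing,
                          affine = p0$affine), class = "tissue_prob")
  structure(list(probabilities = probs, stats = stats,
                 stats_trace = stats_trace, n_iter = iter,
                 converged = converged, delta_trace = delta_trace),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat("segmentation_result:", x$n_iter, "iterations,",
      if (x$converged) "converged" else "NOT converged", "\n")
  if (!is.null(x$stats)) {
    cat("  class means:", paste(sprintf("%s=%.2f", TISSUE_CLASSES,
                                        x$stats$mu), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Otsu's threshold over a 256-bin histogram
#'
#' Exhaustively searches the 255 inter-bin cuts of a 256-bin histogram for
#' the one maximising the between-class variance
#' `w0 w1 (mu0 - mu1)^2`; ties are broken toward the lower threshold. For
#' data inside `[0, 1]` (probability maps) the bins span `[0, 1]`;
#' otherwise they span the data range.
#'
#' @param values numeric vector with at least two distinct values.
#' @return The threshold (a bin edge); foreground is `values > threshold`.
#' @export
otsu_threshold <- function(values) {
  values <- as.numeric(values)
  values <- values[is.finite(values)]
  if (length(unique(values)) < 2L) stop("Otsu threshold undefined for constant input")
  lo <- min(values); hi <- max(values)
  if (lo >= 0 && hi <= 1) { lo <- 0; hi <- 1 }
  nb <- 256L
  edges <- seq(lo, hi, length.out = nb + 1L)
  h <- as.numeric(tabulate(pmin(pmax(findInterval(values, edges, rightmost.closed = TRUE), 1L), nb), nb))
  w <- cumsum(h)
  n <- w[nb]
  mids <- (edges[-1] + edges[-(nb + 1L)]) / 2
  s <- cumsum(h * mids)
  stot <- s[nb]
  t <- seq_len(nb - 1L)
  w0 <- w[t]; w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, nb - 1L)
  bcv[valid] <- (stot * w0[valid] / n - s[t][valid])^2 * n /
    (w0[valid] * w1[valid])
  # first cut on the maximal plateau: ties (exact or to rounding) break
  # toward the lower threshold
  best <- which(bcv >= max(bcv) - 1e-10 * abs(max(bcv)))[1]
  edges[best + 1L]
}

#' Binarise the gray-matter probability map
#'
#' Thresholds the gray-matter membership probabilities at the Otsu cut,
#' yielding the binary gray-matter structure used for shape matching.
#'
#' @param seg a `segmentation_result` (or a `tissue_prob`).
#' @return An object of class `gm_mask`: `mask` (3D 0/1 array),
#'   `threshold`, `spacing`, `affine`.
#' @export
binarize_gray_matter <- function(seg) {
  probs <- if (inherits(seg, "segmentation_result")) seg$probabilities else seg
  stopifnot(inherits(probs, "tissue_prob"))
  gm <- probs$p[, "GM"]
  if (all(gm == 0)) stop("empty gray matter: GM probability is zero everywhere")
  thr <- otsu_threshold(gm)
  mask <- array(as.integer(gm > thr), probs$dim)
  if (sum(mask) == 0L) stop("empty gray matter: no voxel above the Otsu threshold")
  gm_mask(mask, thr, probs$spacing, probs$affine)
}

#' Binary gray-matter mask
#'
#' @param mask 3D array of 0/1 values.
#' @param threshold the probability cut that produced the mask.
#' @param spacing,affine grid metadata as for [brain_volume].
#' @return An object of class `gm_mask`.
#' @export
gm_mask <- function(mask, threshold = 0.5, spacing = c(1, 1, 1),
                    affine = NULL) {
  if (!all(mask %in% c(0L, 1L))) stop("mask values must be 0/1")
  mask <- array(as.integer(mask), dim(mask))
  if (is.null(affine)) affine <- center_affine(dim(mask), spacing)
  structure(list(mask = mask, threshold = threshold,
                 spacing = as.numeric(spacing), affine = as.matrix(affine)),
            class = "gm_mask")
}

#' @export
print.gm_mask <- function(x, ...) {
  cat("gm_mask:", paste(dim(x$mask), collapse = " x "), "voxels,",
      sum(x$mask), "foreground, Otsu threshold",
      signif(x$threshold, 4), "\n")
  invisible(x)
}
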