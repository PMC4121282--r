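# Independent brute-force oracles and small fixture builders used across
# the test files. Everything here is deliberately naive: plain loops and
# closed forms, never the package's own fast paths.

# Directed chamfer distance by the O(n1 * n2) double loop, in mm.
brute_chamfer <- function(m1, m2, spacing) {
  f1 <- which(m1 != 0, arr.ind = TRUE)
  f2 <- which(m2 != 0, arr.ind = TRUE)
  s <- sum(apply(f1, 1, function(v) {
    dx <- sweep(f2, 2, v, "-")
    dx <- sweep(dx, 2, spacing, "*")
    sqrt(min(rowSums(dx^2)))
  }))
  s
}

# Trilinear interpolation of one point (0-based voxel coords) by hand.
brute_trilinear <- function(a, p) {
  dm <- dim(a)
  if (any(p < 0) || any(p > dm - 1)) return(0)
  i0 <- pmin(floor(p), dm - 2); f <- p - i0
  v <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    wgt <- prod(ifelse(c(dx, dy, dz) == 1, f, 1 - f))
    v <- v + wgt * a[i0[1] + dx + 1, i0[2] + dy + 1, i0[3] + dz + 1]
  }
  v
}

# Otsu by exhaustive loop over the 255 cuts of a 256-bin histogram.
brute_otsu <- function(values, lo = 0, hi = 1) {
  nb <- 256
  edges <- seq(lo, hi, length.out = nb + 1)
  bin <- pmin(pmax(findInterval(values, edges, rightmost.closed = TRUE), 1), nb)
  vs <- rep(-Inf, nb - 1)
  mids <- (edges[-1] + edges[-(nb + 1)]) / 2
  for (t in 1:(nb - 1)) {
    g0 <- mids[bin][bin <= t]; g1 <- mids[bin][bin > t]
    if (!length(g0) || !length(g1)) next
    w0 <- length(g0) / length(values); w1 <- 1 - w0
    vs[t] <- w0 * w1 * (mean(g0) - mean(g1))^2
  }
  # lowest cut on the maximal plateau (rounding-robust tie rule)
  best_t <- which(vs >= max(vs) - 1e-10 * abs(max(vs)))[1]
  edges[best_t + 1]
}

# Random binary mask with roughly n_fg foreground voxels.
random_mask <- function(dm, n_fg, spacing = c(1, 1, 1)) {
  m <- array(0L, dm)
  idx <- sample(prod(dm), n_fg)
  m[idx] <- 1L
  gm_mask(m, 0.5, spacing)
}

# Small centred ball volume, handy as a structured fixture.
ball_volume <- function(dm = c(16, 16, 16), radius = 5, spacing = c(1, 1, 1),
                        inside = 100, outside = 0) {
  aff <- diag(c(spacing, 1)); aff[1:3, 4] <- -(dm - 1) / 2 * spacing
  idx <- as.matrix(expand.grid(x = seq_len(dm[1]) - 1, y = seq_len(dm[2]) - 1,
                               z = seq_len(dm[3]) - 1))
  w <- t(aff[1:3, 1:3] %*% t(idx)) + matrix(aff[1:3, 4], nrow(idx), 3,
                                            byrow = TRUE)
  v <- ifelse(sqrt(rowSums(w^2)) < radius, inside, outside)
  brain_volume(array(v, dm), spacing, aff)
}

# A small, fast phantom configuration for pipeline tests.
tiny_config <- function(seed = 1, ...) {
  phantom_config(shape = c(32, 32, 32), spacing = c(1, 1, 1.25),
                 seed = seed, ...)
}
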