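#' Build a 4x4 rigid-body matrix from 6 parameters
#'
#' The transform is the product `Trans(p1,p2,p3) Rx(p4) Ry(p5) Rz(p6)` in
#' homogeneous column-vector convention: translations in mm along x/y/z
#' followed (right-to-left) by proper right-handed rotations about x, y and
#' z in radians. Rotations pivot about the world origin.
#'
#' @param p numeric length-6: `(tx, ty, tz, rx, ry, rz)` in mm / radians.
#' @return A 4x4 matrix with last row `(0,0,0,1)` and an orthonormal
#'   rotation block of determinant +1.
#' @export
build_rigid_matrix <- function(p) {
  p <- as.numeric(p)
  if (length(p) != 6L || any(!is.finite(p)))
    stop("rigid parameters must be 6 finite numbers")
  Rx <- rot3(p[4], 1); Ry <- rot3(p[5], 2); Rz <- rot3(p[6], 3)
  M <- diag(4)
  M[1:3, 1:3] <- Rx %*% Ry %*% Rz
  M[1:3, 4] <- p[1:3]
  M
}

# Partial derivatives of build_rigid_matrix(p) with respect to each of the
# six parameters, as a list of 4x4 matrices.
rigid_matrix_derivs <- function(p) {
  Rx <- rot3(p[4], 1); Ry <- rot3(p[5], 2); Rz <- rot3(p[6], 3)
  dRx <- drot3(p[4], 1); dRy <- drot3(p[5], 2); dRz <- drot3(p[6], 3)
  out <- vector("list", 6)
  for (j in 1:3) {
    E <- matrix(0, 4, 4); E[j, 4] <- 1
    out[[j]] <- E
  }
  blocks <- list(dRx %*% Ry %*% Rz, Rx %*% dRy %*% Rz, Rx %*% Ry %*% dRz)
  for (j in 4:6) {
    D <- matrix(0, 4, 4)
    D[1:3, 1:3] <- blocks[[j - 3]]
    out[[j]] <- D
  }
  out
}

# d/dtheta of rot3(theta, axis).
drot3 <- function(theta, axis) {
  c_ <- cos(theta); s_ <- sin(theta)
  R <- matrix(0, 3, 3)
  ij <- setdiff(1:3, axis)
  R[ij[1], ij[1]] <- -s_; R[ij[2], ij[2]] <- -s_
  sgn <- if (axis == 2) -1 else 1
  R[ij[1], ij[2]] <- -c_ * sgn
  R[ij[2], ij[1]] <- c_ * sgn
  R
}

# Proper right-handed rotation about axis (1=x, 2=y, 3=z).
rot3 <- function(theta, axis) {
  c_ <- cos(theta); s_ <- sin(theta)
  R <- diag(3)
  ij <- setdiff(1:3, axis)
  R[ij[1], ij[1]] <- c_; R[ij[2], ij[2]] <- c_
  sgn <- if (axis == 2) -1 else 1
  R[ij[1], ij[2]] <- -s_ * sgn
  R[ij[2], ij[1]] <- s_ * sgn
  R
}

# TRUE if the 3x3 block of M is orthonormal with determinant +1.
is_rigid_matrix <- function(M, tol = 1e-6) {
  R <- M[1:3, 1:3]
  max(abs(t(R) %*% R - diag(3))) < tol &&
    abs(det(R) - 1) < tol &&
    max(abs(M[4, ] - c(0, 0, 0, 1))) < tol
}

#' Decompose a rigid matrix into its 6 parameters
#'
#' Inverse of [build_rigid_matrix()] for the factor order
#' `Trans Rx(p4) Ry(p5) Rz(p6)`. Rotations are reported wrapped to
#' `(-pi, pi]`. Fails for matrices with scale or shear and at gimbal lock
#' (`|cos p5|` numerically zero), where the x/z rotations are not separable.
#'
#' @param M 4x4 rigid matrix.
#' @return Named numeric vector `(tx, ty, tz, rx, ry, rz)`.
#' @export
decompose_rigid <- function(M) {
  M <- as.matrix(M)
  if (!all(dim(M) == c(4L, 4L))) stop("expected a 4x4 matrix")
  if (!is_rigid_matrix(M)) stop("not rigid: rotation block is not orthonormal with det +1")
  R <- M[1:3, 1:3]
  sy <- max(-1, min(1, R[1, 3]))
  p5 <- asin(sy)
  if (abs(cos(p5)) < 1e-8)
    stop("gimbal lock: |cos(ry)| ~ 0, x/z rotations are degenerate")
  p6 <- atan2(-R[1, 2], R[1, 1])
  p4 <- atan2(-R[2, 3], R[3, 3])
  wrap <- function(a) { a <- (a + pi) %% (2 * pi) - pi; if (a <= -pi) a + 2 * pi else a }
  out <- c(M[1, 4], M[2, 4], M[3, 4], wrap(p4), wrap(p5), wrap(p6))
  names(out) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  out
}

#' Compose the inter-image transform through the template bridge
#'
#' Given the rigid transforms `M1`, `M2` that map image 1 and image 2 into
#' template space, returns the transform carrying image 1 coordinates onto
#' image 2 coordinates, `M2^{-1} M1` (column-vector convention; this is the
#' template-bridge composition, equal to the product of one registration
#' with the explicitly inverted other).
#'
#' @param M1,M2 4x4 invertible matrices mapping each image to the template.
#' @return The 4x4 matrix `solve(M2) %*% M1`.
#' @export
compose_inter_image_transform <- function(M1, M2) {
  M1 <- as.matrix(M1); M2 <- as.matrix(M2)
  if (abs(det(M2)) < 1e-12) stop("M2 is singular")
  solve(M2) %*% M1
}

#' Resample a volume onto a reference grid
#'
#' Pull-back resampling: the output lives on the grid of `reference` and its
#' value at reference voxel `x` (world mm) is `v` sampled at `M^{-1} x`,
#' where `M` maps `v`'s world space onto the reference world space.
#' Out-of-field voxels are set to 0. Nearest mode preserves the value set of
#' binary inputs exactly; linear mode is trilinear.
#'
#' @param v a [brain_volume] to resample.
#' @param M 4x4 invertible world-to-world matrix mapping `v` onto
#'   `reference`.
#' @param reference a [brain_volume] supplying the output grid.
#' @param mode `"linear"` or `"nearest"`.
#' @return A [brain_volume] on the reference grid.
#' @export
resample <- function(v, M, reference, mode = c("linear", "nearest")) {
  mode <- match.arg(mode)
  stopifnot(inherits(v, "brain_volume"), inherits(reference, "brain_volume"))
  M <- as.matrix(M)
  if (abs(det(M)) < 1e-12) stop("transform is singular")
  # target voxel -> target world -> v world (M^-1) -> v voxel
  C <- solve(v$affine) %*% solve(M) %*% reference$affine
  out <- cpp_resample(as.numeric(v$data), dim(v$data), C,
                      dim(reference$data), if (mode == "nearest") 1L else 0L)
  brain_volume(array(out, dim(reference$data)),
               reference$spacing, reference$affine)
}
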