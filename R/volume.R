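#' 3D scalar volume
#'
#' A `brain_volume` is a minimal container for a 3D scalar grid: the voxel
#' data, the per-axis voxel size in mm, and the 4x4 voxel-to-world affine
#' (0-based voxel indices, world coordinates in mm). It is the unit of
#' exchange between the registration, segmentation and matching steps.
#'
#' @param data 3D numeric array with all axis lengths >= 1.
#' @param spacing numeric length-3, voxel size in mm per axis; all > 0.
#' @param affine 4x4 voxel-to-world matrix; defaults to a diagonal affine
#'   with the world origin at the grid centre, so rotations in world space
#'   pivot about the centre of the field of view.
#' @return An object of class `brain_volume` with fields `data`, `spacing`,
#'   `affine`.
#' @export
brain_volume <- function(data, spacing = c(1, 1, 1), affine = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("expected 3D volume, got ", length(dim(data)), " dimensions")
  if (any(dim(data) < 1L)) stop("all axis lengths must be >= 1")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive finite values (mm)")
  if (anyNA(data)) stop("volume data contains NaN/NA values")
  if (any(!is.finite(data))) stop("volume data contains non-finite values")
  if (is.null(affine)) affine <- center_affine(dim(data), spacing)
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L))) stop("affine must be a 4x4 matrix")
  structure(list(data = data, spacing = spacing, affine = affine),
            class = "brain_volume")
}

# Diagonal voxel-to-world affine placing the world origin at the grid centre.
center_affine <- function(dm, spacing) {
  a <- diag(c(spacing, 1))
  a[1:3, 4] <- -(dm - 1) / 2 * spacing
  a
}

#' @export
print.brain_volume <- function(x, ...) {
  cat("brain_volume:", paste(dim(x$data), collapse = " x "),
      "voxels, spacing", paste(signif(x$spacing, 4), collapse = " x "),
      "mm\n  intensity range [", signif(min(x$data), 5), ",",
      signif(max(x$data), 5), "]\n")
  invisible(x)
}

#' Read a 3D NIfTI volume
#'
#' Loads a NIfTI-1 file and returns a [brain_volume] carrying the header
#' voxel spacing and the voxel-to-world affine (sform if set, else qform).
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return A [brain_volume].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  dm <- dim(img)
  if (length(dm) == 4L && dm[4] == 1L) {
    img2 <- array(as.numeric(img), dm[1:3])
    dm <- dm[1:3]
    data <- img2
  } else if (length(dm) != 3L) {
    stop("expected 3D volume in ", path, " (got ", length(dm), "D)")
  } else {
    data <- array(as.numeric(img), dm)
  }
  if (anyNA(data) || any(!is.finite(data)))
    stop("volume contains NaN/Inf voxels: ", path)
  sp <- RNifti::pixdim(img)[1:3]
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  brain_volume(data, spacing = sp, affine = aff)
}

#' Write a volume to NIfTI
#'
#' @param v a [brain_volume].
#' @param path output path (`.nii` or `.nii.gz`); the parent directory must
#'   exist.
#' @param datatype NIfTI storage type, e.g. `"double"` (default, lossless) or
#'   `"uint8"` for binary masks.
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path, datatype = "double") {
  stopifnot(inherits(v, "brain_volume"))
  if (!dir.exists(dirname(path))) stop("directory does not exist: ", dirname(path))
  img <- RNifti::asNifti(v$data)
  RNifti::pixdim(img) <- v$spacing
  RNifti::qform(img) <- structure(v$affine, code = 2L)
  RNifti::sform(img) <- structure(v$affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Gaussian smoothing of a volume
#'
#' Separable Gaussian filter parameterised by full width at half maximum in
#' mm; the per-axis kernel sigma in voxels is
#' `fwhm / (2 sqrt(2 log 2)) / spacing`. Boundaries are handled by symmetric
#' reflection, which preserves both constants and the volume sum.
#'
#' @param v a [brain_volume].
#' @param fwhm_mm kernel full width at half maximum in mm; `0` returns the
#'   input unchanged.
#' @return The smoothed [brain_volume].
#' @export
gaussian_smooth <- function(v, fwhm_mm) {
  stopifnot(inherits(v, "brain_volume"))
  if (!is.finite(fwhm_mm) || fwhm_mm < 0) stop("fwhm_mm must be >= 0")
  if (fwhm_mm == 0) return(v)
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / v$spacing
  out <- v$data
  for (ax in 1:3) out <- convolve_axis(out, ax, sigma_vox[ax])
  brain_volume(out, v$spacing, v$affine)
}

# Convolve one axis with a normalized discrete Gaussian, reflect boundary.
# Implemented as multiplication by an L x L band matrix folded at the edges.
convolve_axis <- function(arr, axis, sigma) {
  if (sigma < 1e-8) return(arr)
  L <- dim(arr)[axis]
  r <- max(1L, ceiling(4 * sigma))
  kern <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  kern <- kern / sum(kern)
  K <- matrix(0, L, L)
  for (o in seq(-r, r)) {
    j <- seq_len(L) + o
    # symmetric half-sample reflection: index i maps to 1-i below, 2L+1-i above
    while (any(j < 1L | j > L)) {
      j <- ifelse(j < 1L, 1L - j, j)
      j <- ifelse(j > L, 2L * L + 1L - j, j)
    }
    K[cbind(seq_len(L), j)] <- K[cbind(seq_len(L), j)] + kern[o + r + 1]
  }
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  dm <- dim(a)
  m <- K %*% matrix(a, nrow = L)
  aperm(array(m, dm), order(perm))
}
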