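TISSUE_CLASSES <- c("GM", "WM", "CSF", "other")

#' Tissue prior set
#'
#' Four aligned probability volumes (gray matter, white matter, CSF, other)
#' on a common grid. Values are clipped to `[0, 1]` and renormalised so the
#' four classes sum to one at every voxel.
#'
#' @param p 4D array `x` x `y` x `z` x 4, class axis ordered GM, WM, CSF,
#'   other.
#' @param spacing,affine grid metadata as for [brain_volume].
#' @return An object of class `tissue_priors` with fields `p` (4D array),
#'   `spacing`, `affine`.
#' @export
tissue_priors <- function(p, spacing = c(1, 1, 1), affine = NULL) {
  if (!is.array(p) || length(dim(p)) != 4L || dim(p)[4] != 4L)
    stop("priors must be a 4D array with 4 classes on the last axis")
  if (anyNA(p)) stop("priors contain NaN/NA")
  if (min(p) < -1e-6 || max(p) > 1 + 1e-6)
    stop("prior values must lie in [0, 1]")
  p <- pmin(pmax(p, 0), 1)
  tot <- p[, , , 1] + p[, , , 2] + p[, , , 3] + p[, , , 4]
  if (any(tot <= 0)) stop("priors sum to zero at some voxels")
  for (k in 1:4) p[, , , k] <- p[, , , k] / tot
  if (is.null(affine)) affine <- center_affine(dim(p)[1:3], spacing)
  dimnames(p) <- list(NULL, NULL, NULL, TISSUE_CLASSES)
  structure(list(p = p, spacing = as.numeric(spacing),
                 affine = as.matrix(affine)),
            class = "tissue_priors")
}

#' @export
print.tissue_priors <- function(x, ...) {
  cat("tissue_priors:", paste(dim(x$p)[1:3], collapse = " x "),
      "voxels, classes", paste(TISSUE_CLASSES, collapse = "/"), "\n")
  invisible(x)
}

#' Read tissue priors from NIfTI
#'
#' Accepts either one 4D NIfTI with the tissue class as the 4th axis
#' (ordered GM, WM, CSF, other) or four 3D files in that order.
#'
#' @param path a single 4D file, or a character vector of four 3D files.
#' @return A [tissue_priors] object (renormalised per voxel).
#' @export
read_priors <- function(path) {
  if (length(path) == 4L) {
    vols <- lapply(path, read_volume)
    p <- array(0, c(dim(vols[[1]]$data), 4))
    for (k in 1:4) p[, , , k] <- vols[[k]]$data
    return(tissue_priors(p, vols[[1]]$spacing, vols[[1]]$affine))
  }
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  dm <- dim(img)
  if (length(dm) != 4L || dm[4] != 4L)
    stop("expected a 4D prior image with 4 classes: ", path)
  sp <- RNifti::pixdim(img)[1:3]
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  tissue_priors(array(as.numeric(img), dm), sp, aff)
}

#' Write tissue priors as one 4D NIfTI
#'
#' @param priors a [tissue_priors] object.
#' @param path output `.nii`/`.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_priors <- function(priors, path) {
  stopifnot(inherits(priors, "tissue_priors"))
  p <- priors$p
  dimnames(p) <- NULL
  img <- RNifti::asNifti(p)
  RNifti::pixdim(img) <- c(priors$spacing, 1)
  RNifti::qform(img) <- structure(priors$affine, code = 2L)
  RNifti::sform(img) <- structure(priors$affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

# Extract one prior class as a brain_volume.
prior_volume <- function(priors, k) {
  brain_volume(priors$p[, , , k, drop = TRUE], priors$spacing, priors$affine)
}
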