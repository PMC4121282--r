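#' Align a binary gray-matter mask onto a reference grid
#'
#' Nearest-neighbour resampling of `B1` onto the grid of `reference` under
#' the inter-image transform `M12` (image-1 world onto image-2 world, as
#' produced by [compose_inter_image_transform()]). The output is strictly
#' binary.
#'
#' @param B1 a [gm_mask] to move.
#' @param M12 4x4 rigid matrix mapping `B1`'s world space onto the
#'   reference world space.
#' @param reference a [gm_mask] supplying the target grid.
#' @return A [gm_mask] on the reference grid.
#' @export
align_mask <- function(B1, M12, reference) {
  stopifnot(inherits(B1, "gm_mask"), inherits(reference, "gm_mask"))
  v <- brain_volume(B1$mask + 0, B1$spacing, B1$affine)
  ref <- brain_volume(reference$mask + 0, reference$spacing, reference$affine)
  out <- resample(v, M12, ref, mode = "nearest")
  gm_mask(array(as.integer(out$data), dim(out$data)), B1$threshold,
          reference$spacing, reference$affine)
}

#' Directed chamfer distance between two binary masks
#'
#' For every foreground voxel of `B1p`, the Euclidean distance in mm
#' (anisotropic voxel spacing respected) to the nearest foreground voxel of
#' `B2p`, summed. Computed through the exact Euclidean distance transform of
#' `B2p`, which equals the brute-force nearest-neighbour double loop. The
#' distance is directed: swapping the arguments generally changes the value.
#'
#' @param B1p,B2p [gm_mask] objects on the same grid, both with non-empty
#'   foreground.
#' @param symmetric if `TRUE`, average the two directed sums.
#' @param per_voxel if `TRUE`, divide by the number of foreground voxels of
#'   the moving mask (per direction).
#' @return The chamfer distance in mm (a sum over foreground voxels unless
#'   `per_voxel`).
#' @export
chamfer_distance <- function(B1p, B2p, symmetric = FALSE, per_voxel = FALSE) {
  stopifnot(inherits(B1p, "gm_mask"), inherits(B2p, "gm_mask"))
  if (!all(dim(B1p$mask) == dim(B2p$mask)))
    stop("masks must share a grid")
  n1 <- sum(B1p$mask); n2 <- sum(B2p$mask)
  if (n1 == 0L || n2 == 0L) stop("cannot match empty mask")
  directed <- function(a, b) {
    d2 <- cpp_edt_sq(as.logical(b$mask), dim(b$mask), b$spacing)
    sum(sqrt(d2[as.logical(a$mask)]))
  }
  d <- directed(B1p, B2p)
  if (per_voxel) d <- d / n1
  if (symmetric) {
    dr <- directed(B2p, B1p)
    if (per_voxel) dr <- dr / n2
    d <- (d + dr) / 2
  }
  d
}

#' Train the linear score normaliser
#'
#' The normaliser maps chamfer distances to similarity scores in
#' `[0, 100]`; its anchors are the minimum and maximum distance observed in
#' a training collection of pair distances.
#'
#' @param training_distances numeric vector of chamfer distances with at
#'   least two distinct values.
#' @return An object of class `score_normalizer` with fields `dmin`, `dmax`.
#' @export
fit_normalizer <- function(training_distances) {
  d <- as.numeric(training_distances)
  d <- d[is.finite(d)]
  if (length(unique(d)) < 2L)
    stop("need at least two distinct training distances")
  structure(list(dmin = min(d), dmax = max(d)), class = "score_normalizer")
}

#' Normalise a chamfer distance to a similarity score
#'
#' Linear map `s = (1 - (d - dmin)/(dmax - dmin)) * 100`, clamped to
#' `[0, 100]`: the trained minimum distance scores 100 (full matching), the
#' trained maximum scores 0 (mismatch).
#'
#' @param d chamfer distance(s).
#' @param norm a `score_normalizer`.
#' @return Score(s) in `[0, 100]`.
#' @export
normalize_score <- function(d, norm) {
  stopifnot(inherits(norm, "score_normalizer"))
  s <- (1 - (d - norm$dmin) / (norm$dmax - norm$dmin)) * 100
  pmin(pmax(s, 0), 100)
}

#' Save / load a score normaliser as JSON
#' @param norm a `score_normalizer`.
#' @param path JSON file path.
#' @return `path` invisibly; `load_normalizer()` returns the
#'   `score_normalizer`.
#' @export
save_normalizer <- function(norm, path) {
  jsonlite::write_json(list(dmin = norm$dmin, dmax = norm$dmax), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_normalizer
#' @export
load_normalizer <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(dmin = as.numeric(obj$dmin), dmax = as.numeric(obj$dmax)),
            class = "score_normalizer")
}

#' Match a pair of brain volumes end to end
#'
#' Full verification pipeline for one image pair: both volumes are rigidly
#' registered to the template, segmented with the prior-guided mixture
#' model, and their gray matter binarised; the inter-image transform is
#' composed through the template bridge, the first mask aligned onto the
#' second, and the directed chamfer distance computed and normalised.
#'
#' @param I1,I2 [brain_volume] inputs (I1 is moved onto I2's grid).
#' @param template template [brain_volume].
#' @param priors [tissue_priors] in template space.
#' @param norm a `score_normalizer`.
#' @param reg_cfg,seg_cfg settings for registration and segmentation.
#' @param symmetric,per_voxel chamfer options, see [chamfer_distance()].
#' @return An object of class `match_result`: `d` (mm), `s` (score),
#'   `n_fg_1`, `n_fg_2`, `transform` (4x4 inter-image matrix),
#'   `thresholds` (Otsu cuts used for the two masks).
#' @export
match_pair <- function(I1, I2, template, priors, norm,
                       reg_cfg = registration_settings(),
                       seg_cfg = segmentation_settings(),
                       symmetric = FALSE, per_voxel = FALSE) {
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e)
      stop(what, ": ", conditionMessage(e), call. = FALSE))
  }
  r1 <- stage("registration (image 1)", estimate_rigid(I1, template, reg_cfg))
  r2 <- stage("registration (image 2)", estimate_rigid(I2, template, reg_cfg))
  s1 <- stage("segmentation (image 1)", em_segment(I1, priors, r1$matrix, seg_cfg))
  s2 <- stage("segmentation (image 2)", em_segment(I2, priors, r2$matrix, seg_cfg))
  B1 <- stage("binarization (image 1)", binarize_gray_matter(s1))
  B2 <- stage("binarization (image 2)", binarize_gray_matter(s2))
  M12 <- compose_inter_image_transform(r1$matrix, r2$matrix)
  B1p <- stage("alignment", align_mask(B1, M12, B2))
  d <- stage("chamfer matching",
             chamfer_distance(B1p, B2, symmetric = symmetric,
                              per_voxel = per_voxel))
  s <- normalize_score(d, norm)
  structure(list(d = d, s = s, n_fg_1 = sum(B1p$mask), n_fg_2 = sum(B2$mask),
                 transform = M12,
                 thresholds = c(B1$threshold, B2$threshold)),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat("match_result: d =", signif(x$d, 6), "mm, score =",
      signif(x$s, 4), "\n  foreground:", x$n_fg_1, "vs", x$n_fg_2,
      "voxels\n")
  invisible(x)
}
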