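#' Phantom generator configuration
#'
#' Settings for the synthetic brain phantom: a head modelled as nested
#' ellipsoidal tissue shells (WM core, GM shell, CSF shell, other outside)
#' whose boundaries are perturbed per subject by a band-limited radial
#' field. Visits of a subject share the anatomy exactly and differ by a
#' rigid motion, a global intensity gain, and additive Gaussian noise —
#' the degradation factors a repeat structural MRI acquisition exhibits.
#'
#' @param shape grid size per axis (all >= 32).
#' @param spacing voxel size in mm (default 1 x 1 x 1.25, the in-plane /
#'   slice geometry of a typical MP-RAGE acquisition).
#' @param intensities named class intensities on a nominal 0-100 scale,
#'   strictly ordered other < CSF < GM < WM.
#' @param noise_sd additive Gaussian noise s.d. as a fraction of the
#'   nominal 100-unit intensity scale (default 0.02, the bottom of the
#'   1.5 T SNR band).
#' @param deform_amplitude s.d. of the subject-specific radial boundary
#'   perturbation as a fraction of head radius (default 0.06).
#' @param n_harmonics number of low-order angular basis terms in the
#'   perturbation field (>= 3).
#' @param motion_t,motion_r per-visit rigid motion ranges: translations
#'   drawn uniformly in `[-motion_t, motion_t]` mm, rotations in
#'   `[-motion_r, motion_r]` degrees.
#' @param gain_range per-visit global intensity gain, drawn uniformly.
#' @param seed base random seed; all generator output is a pure function of
#'   the configuration including this seed.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(shape = c(64, 64, 48), spacing = c(1, 1, 1.25),
                           intensities = c(other = 5, CSF = 25, GM = 55,
                                           WM = 85),
                           noise_sd = 0.02, deform_amplitude = 0.06,
                           n_harmonics = 6L, motion_t = 5, motion_r = 5,
                           gain_range = c(0.9, 1.1), seed = 42L) {
  if (any(shape < 32)) stop("phantom grid must be >= 32 voxels per axis")
  if (deform_amplitude < 0 || noise_sd < 0) stop("amplitudes must be >= 0")
  ints <- intensities[c("other", "CSF", "GM", "WM")]
  if (anyNA(ints) || any(diff(ints) <= 0))
    stop("intensities must be named and strictly ordered other < CSF < GM < WM")
  if (n_harmonics < 3L) stop("need at least 3 harmonics")
  structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                 intensities = ints, noise_sd = noise_sd,
                 deform_amplitude = deform_amplitude,
                 n_harmonics = as.integer(n_harmonics),
                 motion_t = motion_t, motion_r = motion_r,
                 gain_range = as.numeric(gain_range),
                 seed = as.integer(seed)),
            class = "phantom_config")
}

# Normalized shell radii (fractions of the head semi-axes). The GM band is
# kept thin (~4 mm at the default grid), in line with cortical thickness,
# which is what makes the gray-matter shape discriminative across subjects.
PHANTOM_RADII <- c(wm = 0.62, gm = 0.78, csf = 0.90)

# Band-limited real angular basis evaluated at unit directions (n x 3).
# Third/fourth-order harmonics only: first/second-order radial perturbations
# of an ellipsoid are near-degenerate with rigid translations/rotations and
# would be absorbed into the estimated pose instead of acting as anatomy.
angular_basis <- function(u) {
  x <- u[, 1]; y <- u[, 2]; z <- u[, 3]
  cbind(x * y * z,
        x * (x^2 - 3 * y^2),
        y * (3 * x^2 - y^2),
        z * (x^2 - y^2),
        x * (5 * z^2 - 1),
        y * (5 * z^2 - 1),
        z * (5 * z^2 - 3),
        x * y * (x^2 - y^2),
        35 * z^4 - 30 * z^2 + 3)
}

# World-mm coordinates of every voxel of a grid (n x 3), given the affine.
grid_world <- function(shape, affine) {
  ix <- rep(seq_len(shape[1]) - 1, times = shape[2] * shape[3])
  iy <- rep(rep(seq_len(shape[2]) - 1, each = shape[1]), times = shape[3])
  iz <- rep(seq_len(shape[3]) - 1, each = shape[1] * shape[2])
  cbind(affine[1, 1] * ix + affine[1, 2] * iy + affine[1, 3] * iz + affine[1, 4],
        affine[2, 1] * ix + affine[2, 2] * iy + affine[2, 3] * iz + affine[2, 4],
        affine[3, 1] * ix + affine[3, 2] * iy + affine[3, 3] * iz + affine[3, 4])
}

# Classify world-mm points into 1=GM, 2=WM, 3=CSF, 4=other for a subject's
# perturbation coefficients.
classify_points <- function(w, coef, cfg) {
  # triaxial head: distinct semi-axes (longer anterior-posterior) so all
  # three rotations are identifiable from the outline alone
  semi <- c(0.36, 0.45, 0.40) * cfg$shape * cfg$spacing
  s <- sweep(w, 2, semi, "/")
  rho <- sqrt(rowSums(s^2))
  r <- sqrt(rowSums(w^2))
  u <- w / pmax(r, 1e-9)
  delta <- if (all(coef == 0)) 0 else as.numeric(angular_basis(u) %*% coef)
  scale <- 1 + delta
  lab <- rep(4L, nrow(w))
  lab[rho < PHANTOM_RADII["csf"] * scale] <- 3L
  lab[rho < PHANTOM_RADII["gm"] * scale] <- 1L
  lab[rho < PHANTOM_RADII["wm"] * scale] <- 2L
  # paired lateral "ventricles": CSF pockets inside the WM core, displaced
  # anteriorly, laterally and upward; together with the fissure below they
  # anchor all three rotations the way real deep structure does
  vsemi <- c(0.16, 0.30, 0.16) * semi
  for (sgn in c(-1, 1)) {
    ctr <- c(sgn * 0.26, 0.16, 0.12) * semi
    sv <- sweep(w, 2, ctr, "-")
    sv <- sweep(sv, 2, vsemi, "/")
    inside <- rowSums(sv^2) < 1
    lab[inside & lab == 2L] <- 3L
  }
  # interhemispheric "fissure": a thin midsagittal CSF slab through the
  # upper half of the head, splitting the WM/GM into hemispheres
  fis <- abs(w[, 1]) < 1.5 & w[, 3] > -0.2 * semi[3] & rho > 0.25
  lab[fis & lab %in% c(1L, 2L)] <- 3L
  lab
}

#' Generate a subject's ground-truth anatomy
#'
#' Draws a subject-specific band-limited radial perturbation of the tissue
#' shell boundaries (s.d. = `deform_amplitude` of head radius over the
#' sphere) and renders the ground-truth label volume in template space.
#' Zero amplitude makes every subject identical to the template anatomy.
#'
#' @param cfg a [phantom_config()].
#' @param subject_seed integer seed identifying the subject.
#' @return An object of class `subject_truth`: `coef` (perturbation
#'   coefficients), `labels` (a [brain_volume] of class codes 1=GM, 2=WM,
#'   3=CSF, 4=other), `cfg`, `subject_seed`.
#' @export
generate_subject <- function(cfg, subject_seed) {
  stopifnot(inherits(cfg, "phantom_config"))
  subject_seed <- as.integer(subject_seed)
  if (is.na(subject_seed)) stop("invalid subject seed")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(subject_seed)
  nh <- min(9L, cfg$n_harmonics)
  coef <- numeric(9)
  coef[seq_len(nh)] <- rnorm(nh)
  # scale the combined field to s.d. = deform_amplitude over the sphere
  field_sd <- stats::sd(angular_basis(fib_dirs()) %*% coef)
  coef <- coef / max(field_sd, 1e-12) * cfg$deform_amplitude
  aff <- center_affine(cfg$shape, cfg$spacing)
  w <- grid_world(cfg$shape, aff)
  lab <- classify_points(w, coef, cfg)
  labels <- brain_volume(array(as.numeric(lab), cfg$shape), cfg$spacing, aff)
  structure(list(coef = coef, labels = labels, cfg = cfg,
                 subject_seed = subject_seed),
            class = "subject_truth")
}

# Fixed quasi-uniform unit directions (Fibonacci sphere), for field scaling.
fib_dirs <- function(n = 2000) {
  i <- seq_len(n)
  phi <- acos(1 - 2 * (i - 0.5) / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Generate the template and tissue priors
#'
#' Averages the one-hot tissue labels of 8 seeded virtual subjects, smooths
#' each class with a 3 mm FWHM Gaussian and renormalises per voxel, giving
#' soft population priors; the template intensity volume is the
#' prior-weighted mixture of the class intensities.
#'
#' @param cfg a [phantom_config()].
#' @return List with `template` (a [brain_volume]) and `priors`
#'   (a [tissue_priors]).
#' @export
generate_template <- function(cfg) {
  stopifnot(inherits(cfg, "phantom_config"))
  n_virt <- 8L
  seeds <- derive_seeds(cfg$seed, n_virt, salt = 101L)
  acc <- array(0, c(cfg$shape, 4))
  for (s in seeds) {
    tr <- generate_subject(cfg, s)
    lab <- tr$labels$data
    for (k in 1:4) acc[, , , k] <- acc[, , , k] + (lab == k) / n_virt
  }
  aff <- center_affine(cfg$shape, cfg$spacing)
  for (k in 1:4) {
    acc[, , , k] <- gaussian_smooth(
      brain_volume(acc[, , , k, drop = TRUE], cfg$spacing, aff), 3)$data
  }
  priors <- tissue_priors(acc, cfg$spacing, aff)
  tmpl <- priors$p[, , , 1] * cfg$intensities["GM"] +
    priors$p[, , , 2] * cfg$intensities["WM"] +
    priors$p[, , , 3] * cfg$intensities["CSF"] +
    priors$p[, , , 4] * cfg$intensities["other"]
  list(template = brain_volume(tmpl, cfg$spacing, aff), priors = priors)
}

# Deterministic child seeds below 2^31, derived from a base seed.
derive_seeds <- function(seed, n, salt = 1L) {
  (as.numeric(seed) * 7919 + salt * 104729 + 65537 * seq_len(n)) %% 2147483647
}

#' Render one visit of a subject
#'
#' Draws a rigid head motion (uniform within the configured ranges) and a
#' global intensity gain, renders the class intensities analytically at the
#' moved voxel positions, and adds Gaussian noise. The returned matrix is
#' the ground-truth transform mapping the visit's world coordinates onto
#' template (anatomy) space — the same direction [estimate_rigid()]
#' recovers.
#'
#' @param truth a `subject_truth`.
#' @param visit_seed integer seed for this visit.
#' @param cfg a [phantom_config()]; defaults to the subject's.
#' @param motion optional length-6 rigid parameters overriding the draw.
#' @param gain optional gain overriding the draw.
#' @return List with `volume` ([brain_volume]), `matrix` (4x4 ground
#'   truth), `params` (length-6), `gain`, `visit_seed`.
#' @export
generate_visit <- function(truth, visit_seed, cfg = truth$cfg,
                           motion = NULL, gain = NULL) {
  stopifnot(inherits(truth, "subject_truth"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(visit_seed))
  if (is.null(motion))
    motion <- c(runif(3, -cfg$motion_t, cfg$motion_t),
                runif(3, -cfg$motion_r, cfg$motion_r) * pi / 180)
  if (is.null(gain)) gain <- runif(1, cfg$gain_range[1], cfg$gain_range[2])
  M <- build_rigid_matrix(motion)
  aff <- center_affine(cfg$shape, cfg$spacing)
  w <- grid_world(cfg$shape, aff)
  # anatomy-space position of each visit voxel: M maps visit world -> template
  wa <- w %*% t(M[1:3, 1:3]) + matrix(M[1:3, 4], nrow(w), 3, byrow = TRUE)
  lab <- classify_points(wa, truth$coef, cfg)
  vals <- cfg$intensities[c(3, 4, 2, 1)][lab] * gain
  if (cfg$noise_sd > 0) vals <- vals + rnorm(length(vals), 0, cfg$noise_sd * 100)
  list(volume = brain_volume(array(vals, cfg$shape), cfg$spacing, aff),
       matrix = M, params = motion, gain = gain,
       visit_seed = as.integer(visit_seed))
}

#' Generate a multi-subject, multi-visit cohort
#'
#' Produces a full synthetic verification cohort: template, priors, and
#' `n_subjects * n_visits` volumes with ground-truth anatomy, motion and
#' gain. Fully reproducible from the configuration seed. When `out_dir` is
#' given, all volumes, the template, the priors, per-subject label volumes
#' and a `manifest.csv` are written to disk.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param n_visits visits per subject (>= 2).
#' @param cfg a [phantom_config()].
#' @param out_dir optional output directory.
#' @param share_anatomy optional integer pair `c(a, b)`: subject `b` reuses
#'   subject `a`'s anatomy exactly (a monozygotic-twin stress case for the
#'   verifier).
#' @return List with `template`, `priors`, `manifest` (data frame with
#'   `subject_id`, `visit_id`, ground-truth motion `tx..rz`, `gain`,
#'   `seed`, a `volume` list column and, when written, `path`), and
#'   `truths` (per-subject `subject_truth`).
#' @export
generate_cohort <- function(n_subjects, n_visits, cfg = phantom_config(),
                            out_dir = NULL, share_anatomy = NULL) {
  stopifnot(n_subjects >= 2, n_visits >= 2)
  tp <- generate_template(cfg)
  subj_seeds <- derive_seeds(cfg$seed, n_subjects, salt = 211L)
  visit_seeds <- matrix(derive_seeds(cfg$seed, n_subjects * n_visits,
                                     salt = 307L),
                        n_subjects, n_visits)
  truths <- lapply(subj_seeds, function(s) generate_subject(cfg, s))
  if (!is.null(share_anatomy)) {
    a <- share_anatomy[1]; b <- share_anatomy[2]
    truths[[b]] <- truths[[a]]
  }
  rows <- list()
  vols <- list()
  idx <- 0L
  for (i in seq_len(n_subjects)) {
    for (v in seq_len(n_visits)) {
      idx <- idx + 1L
      vis <- generate_visit(truths[[i]], visit_seeds[i, v], cfg)
      vols[[idx]] <- vis$volume
      rows[[idx]] <- data.frame(
        subject_id = sprintf("sub%02d", i), visit_id = sprintf("v%d", v),
        tx = vis$params[1], ty = vis$params[2], tz = vis$params[3],
        rx = vis$params[4], ry = vis$params[5], rz = vis$params[6],
        gain = vis$gain, seed = vis$visit_seed, stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  manifest$volume <- vols
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!dir.exists(out_dir)) stop("cannot create directory: ", out_dir)
    write_volume(tp$template, file.path(out_dir, "template.nii.gz"))
    write_priors(tp$priors, file.path(out_dir, "priors.nii.gz"))
    paths <- character(nrow(manifest))
    for (r in seq_len(nrow(manifest))) {
      fn <- sprintf("%s_%s.nii.gz", manifest$subject_id[r],
                    manifest$visit_id[r])
      write_volume(manifest$volume[[r]], file.path(out_dir, fn))
      paths[r] <- file.path(out_dir, fn)
    }
    for (i in seq_len(n_subjects))
      write_volume(truths[[i]]$labels,
                   file.path(out_dir, sprintf("sub%02d_labels.nii.gz", i)),
                   datatype = "uint8")
    manifest$path <- paths
    utils::write.csv(manifest[, setdiff(names(manifest), "volume")],
                     file.path(out_dir, "manifest.csv"), row.names = FALSE)
  }
  list(template = tp$template, priors = tp$priors, manifest = manifest,
       truths = truths)
}

#' Dice overlap between two binary masks
#'
#' @param a,b binary arrays (or [gm_mask] objects) on the same grid.
#' @return `2 |A & B| / (|A| + |B|)`.
#' @export
dice_overlap <- function(a, b) {
  if (inherits(a, "gm_mask")) a <- a$mask
  if (inherits(b, "gm_mask")) b <- b$mask
  a <- a > 0; b <- b > 0
  2 * sum(a & b) / (sum(a) + sum(b))
}
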