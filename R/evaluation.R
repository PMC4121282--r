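#' Enumerate genuine and imposter pairs of a cohort
#'
#' Genuine pairs are all same-subject cross-visit pairs; imposter pairs are
#' all cross-subject pairs, by default using each subject's first visit
#' only (so genuine and imposter counts stay comparable). Each unordered
#' pair appears once.
#'
#' @param manifest data frame with columns `subject_id` and `visit_id`
#'   (rows in cohort order).
#' @param imposter_visits `"first"` or `"all"`.
#' @return List with data frames `genuine` (`idx_a`, `idx_b`, `subject`,
#'   `visit_a`, `visit_b`) and `imposter` (`idx_a`, `idx_b`, `subject_a`,
#'   `subject_b`).
#' @export
cohort_pairs <- function(manifest, imposter_visits = c("first", "all")) {
  imposter_visits <- match.arg(imposter_visits)
  subj <- as.character(manifest$subject_id)
  vis <- as.character(manifest$visit_id)
  n <- nrow(manifest)
  gen <- NULL
  for (s in unique(subj)) {
    ix <- which(subj == s)
    if (length(ix) < 2L) next
    cmb <- utils::combn(ix, 2L)
    gen <- rbind(gen, data.frame(idx_a = cmb[1, ], idx_b = cmb[2, ],
                                 subject = s, visit_a = vis[cmb[1, ]],
                                 visit_b = vis[cmb[2, ]],
                                 stringsAsFactors = FALSE))
  }
  if (is.null(gen)) stop("no genuine pairs: need a subject with >= 2 visits")
  if (imposter_visits == "first") {
    firsts <- vapply(unique(subj), function(s) which(subj == s)[1], 1L)
    pool <- firsts
  } else pool <- seq_len(n)
  imp <- NULL
  if (length(unique(subj)) < 2L) stop("no imposter pairs: need >= 2 subjects")
  cmb <- utils::combn(pool, 2L)
  keep <- subj[cmb[1, ]] != subj[cmb[2, ]]
  imp <- data.frame(idx_a = cmb[1, keep], idx_b = cmb[2, keep],
                    subject_a = subj[cmb[1, keep]],
                    subject_b = subj[cmb[2, keep]],
                    stringsAsFactors = FALSE)
  list(genuine = gen, imposter = imp)
}

# Register + segment + binarise every cohort volume once; returns per-volume
# list(volume, reg, mask).
process_cohort <- function(volumes, template, priors,
                           reg_cfg = registration_settings(),
                           seg_cfg = segmentation_settings(),
                           keep_volumes = FALSE) {
  lapply(volumes, function(v) {
    reg <- estimate_rigid(v, template, reg_cfg)
    seg <- em_segment(v, priors, reg$matrix, seg_cfg)
    mask <- binarize_gray_matter(seg)
    list(volume = if (keep_volumes) v else NULL, reg = reg, mask = mask)
  })
}

#' Score a verification cohort
#'
#' Runs the full pipeline over a cohort: each volume is registered to the
#' template, segmented and binarised once; every genuine (same subject,
#' different visits) and imposter (different subjects) pair is then scored
#' by the aligned chamfer distance. The score normaliser is trained on the
#' pooled pair distances of this cohort unless one is supplied. Optionally
#' also computes the raw-intensity baseline scores on the same pairs.
#'
#' @param cohort a data frame with columns `subject_id`, `visit_id` and
#'   either `path` (NIfTI files) or a list column `volume` of
#'   [brain_volume] objects.
#' @param template,priors template [brain_volume] and [tissue_priors].
#' @param reg_cfg,seg_cfg pipeline settings.
#' @param norm optional pre-trained `score_normalizer`; `NULL` trains on
#'   this cohort's all-pairs distances.
#' @param normalizer_pairs `"all"` (default) or `"genuine"`: which pair
#'   distances train the normaliser.
#' @param imposter_visits see [cohort_pairs()].
#' @param symmetric,per_voxel chamfer options.
#' @param baseline if `TRUE`, also return intensity-baseline scores.
#' @return An object of class `score_set`: data frames `genuine` and
#'   `imposter` (pair labels, distance `d`, score `s`), the `normalizer`,
#'   and when `baseline = TRUE` a `baseline` `score_set` whose `d` is the
#'   mean squared intensity difference.
#' @export
score_cohort <- function(cohort, template, priors,
                         reg_cfg = registration_settings(),
                         seg_cfg = segmentation_settings(),
                         norm = NULL, normalizer_pairs = c("all", "genuine"),
                         imposter_visits = c("first", "all"),
                         symmetric = FALSE, per_voxel = FALSE,
                         baseline = FALSE) {
  normalizer_pairs <- match.arg(normalizer_pairs)
  pairs <- cohort_pairs(cohort, match.arg(imposter_visits))
  volumes <- if (!is.null(cohort$volume)) cohort$volume
             else lapply(cohort$path, read_volume)
  proc <- process_cohort(volumes, template, priors, reg_cfg, seg_cfg,
                         keep_volumes = baseline)
  score_dist <- function(ia, ib) {
    M12 <- compose_inter_image_transform(proc[[ia]]$reg$matrix,
                                         proc[[ib]]$reg$matrix)
    B1p <- align_mask(proc[[ia]]$mask, M12, proc[[ib]]$mask)
    chamfer_distance(B1p, proc[[ib]]$mask, symmetric = symmetric,
                     per_voxel = per_voxel)
  }
  dg <- mapply(score_dist, pairs$genuine$idx_a, pairs$genuine$idx_b)
  di <- mapply(score_dist, pairs$imposter$idx_a, pairs$imposter$idx_b)
  if (is.null(norm)) {
    train <- if (normalizer_pairs == "all") c(dg, di) else dg
    norm <- fit_normalizer(train)
  }
  out <- structure(list(
    genuine = cbind(pairs$genuine, d = dg, s = normalize_score(dg, norm)),
    imposter = cbind(pairs$imposter, d = di, s = normalize_score(di, norm)),
    normalizer = norm), class = "score_set")
  if (baseline) {
    base_dist <- function(ia, ib) {
      M12 <- compose_inter_image_transform(proc[[ia]]$reg$matrix,
                                           proc[[ib]]$reg$matrix)
      -intensity_baseline_score(volumes[[ia]], volumes[[ib]], M12)
    }
    bg <- mapply(base_dist, pairs$genuine$idx_a, pairs$genuine$idx_b)
    bi <- mapply(base_dist, pairs$imposter$idx_a, pairs$imposter$idx_b)
    bnorm <- fit_normalizer(c(bg, bi))
    out$baseline <- structure(list(
      genuine = cbind(pairs$genuine, d = bg, s = normalize_score(bg, bnorm)),
      imposter = cbind(pairs$imposter, d = bi, s = normalize_score(bi, bnorm)),
      normalizer = bnorm), class = "score_set")
  }
  out
}

#' @export
print.score_set <- function(x, ...) {
  cat("score_set: ", nrow(x$genuine), " genuine pairs (scores ",
      signif(min(x$genuine$s), 4), "-", signif(max(x$genuine$s), 4), "), ",
      nrow(x$imposter), " imposter pairs (scores ",
      signif(min(x$imposter$s), 4), "-", signif(max(x$imposter$s), 4),
      ")\n", sep = "")
  invisible(x)
}

#' FAR/FRR/TAR table over a threshold sweep
#'
#' At each threshold the false rejection rate is the fraction of genuine
#' pairs scoring below it, the false acceptance rate the fraction of
#' imposter pairs scoring at or above it (scores equal to the threshold are
#' accepted), and the true acceptance rate is `1 - FAR`.
#'
#' @param scores a `score_set` (from [score_cohort()]).
#' @param thresholds numeric vector of score thresholds.
#' @return Data frame with columns `threshold`, `far`, `frr`, `tar`.
#' @export
rate_table <- function(scores, thresholds) {
  stopifnot(inherits(scores, "score_set"))
  g <- scores$genuine$s; i <- scores$imposter$s
  if (length(g) == 0L || length(i) == 0L)
    stop("empty genuine or imposter score list")
  data.frame(threshold = thresholds,
             far = vapply(thresholds, function(t) mean(i >= t), 1),
             frr = vapply(thresholds, function(t) mean(g < t), 1),
             tar = vapply(thresholds, function(t) 1 - mean(i >= t), 1))
}

#' Equal error rate
#'
#' The common FAR = FRR value, obtained by sweeping the threshold across
#' the pooled scores and linearly interpolating the two empirical step
#' curves between the straddling thresholds. Perfectly separated score sets
#' give 0; identically distributed sets give 0.5.
#'
#' @param scores a `score_set`, or a numeric vector of genuine scores.
#' @param imposter imposter scores when `scores` is a plain vector.
#' @return The equal error rate as a fraction in `[0, 0.5]`-ish range.
#' @export
equal_error_rate <- function(scores, imposter = NULL) {
  if (inherits(scores, "score_set")) {
    g <- scores$genuine$s; i <- scores$imposter$s
  } else { g <- as.numeric(scores); i <- as.numeric(imposter) }
  if (length(g) == 0L || length(i) == 0L)
    stop("empty genuine or imposter score list")
  ts <- sort(unique(c(g, i)))
  ts <- c(ts, ts[length(ts)] + 1)  # sentinel: everything rejected
  far <- vapply(ts, function(t) mean(i >= t), 1)
  frr <- vapply(ts, function(t) mean(g < t), 1)
  dd <- far - frr  # non-increasing in the threshold
  j <- which(dd <= 0)[1]
  if (dd[j] == 0) return(far[j])
  # linear interpolation between thresholds j-1 and j
  d1 <- dd[j - 1]; d2 <- dd[j]
  a <- d1 / (d1 - d2)
  far[j - 1] + a * (far[j] - far[j - 1])
}

#' Raw-intensity matching baseline
#'
#' The comparison baseline that matches voxel intensities directly: image 1
#' is resampled onto image 2 under the inter-image transform and the
#' similarity is the negative mean squared intensity difference over the
#' overlapping field of view (optionally mapped through a linear
#' `score_normalizer` trained on such distances). Unlike the binarised
#' gray-matter shape score, this similarity degrades under global intensity
#' rescaling between visits.
#'
#' @param I1,I2 [brain_volume] inputs.
#' @param M12 4x4 matrix mapping image-1 world space onto image-2 world
#'   space.
#' @param norm optional `score_normalizer` over mean-squared-difference
#'   distances.
#' @return Negative mean squared difference (or a `[0,100]` score when
#'   `norm` is supplied).
#' @export
intensity_baseline_score <- function(I1, I2, M12, norm = NULL) {
  stopifnot(inherits(I1, "brain_volume"), inherits(I2, "brain_volume"))
  moved <- resample(I1, M12, I2, mode = "linear")
  inside <- resample(brain_volume(array(1, dim(I1$data)), I1$spacing,
                                  I1$affine),
                     M12, I2, mode = "nearest")$data > 0
  if (!any(inside)) stop("no overlap between the two volumes")
  mse <- mean((moved$data[inside] - I2$data[inside])^2)
  if (is.null(norm)) -mse else normalize_score(mse, norm)
}

#' Write the evaluation report
#'
#' Writes the score table (`scores.csv`), the threshold sweep
#' (`rates.csv`), a genuine/imposter score histogram
#' (`score_histogram.png`), the FAR-vs-FRR curves (`far_frr.png`) and a
#' `summary.json` with the EER and score summaries.
#'
#' @param scores a `score_set`.
#' @param rates a rate table from [rate_table()].
#' @param eer the equal error rate.
#' @param out_dir output directory (created if missing).
#' @return Character vector of the files written, invisibly.
#' @export
report <- function(scores, rates, eer, out_dir) {
  stopifnot(inherits(scores, "score_set"))
  if (nrow(scores$genuine) == 0L || nrow(scores$imposter) == 0L)
    stop("empty genuine or imposter score list")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create directory: ", out_dir)
  g <- scores$genuine; i <- scores$imposter
  sc <- rbind(
    data.frame(pair_id = sprintf("g%03d", seq_len(nrow(g))), type = "genuine",
               id_a = paste0(g$subject, "/", g$visit_a),
               id_b = paste0(g$subject, "/", g$visit_b),
               d = g$d, s = g$s, stringsAsFactors = FALSE),
    data.frame(pair_id = sprintf("i%03d", seq_len(nrow(i))), type = "imposter",
               id_a = i$subject_a, id_b = i$subject_b,
               d = i$d, s = i$s, stringsAsFactors = FALSE))
  f_scores <- file.path(out_dir, "scores.csv")
  f_rates <- file.path(out_dir, "rates.csv")
  f_hist <- file.path(out_dir, "score_histogram.png")
  f_roc <- file.path(out_dir, "far_frr.png")
  f_sum <- file.path(out_dir, "summary.json")
  write.csv(sc, f_scores, row.names = FALSE)
  write.csv(rates, f_rates, row.names = FALSE)
  grDevices::png(f_hist, width = 700, height = 500)
  brk <- seq(0, 100, by = 2.5)
  hg <- graphics::hist(g$s, breaks = brk, plot = FALSE)
  hi <- graphics::hist(i$s, breaks = brk, plot = FALSE)
  ylim <- c(0, max(hg$counts, hi$counts))
  graphics::plot(hi, col = grDevices::rgb(0.8, 0.2, 0.2, 0.5), ylim = ylim,
                 main = "Genuine vs imposter matching scores",
                 xlab = "normalized score", border = NA)
  graphics::plot(hg, col = grDevices::rgb(0.2, 0.4, 0.8, 0.5), add = TRUE,
                 border = NA)
  graphics::legend("top", fill = c(grDevices::rgb(0.2, 0.4, 0.8, 0.5),
                                   grDevices::rgb(0.8, 0.2, 0.2, 0.5)),
                   legend = c("genuine", "imposter"), bty = "n")
  grDevices::dev.off()
  grDevices::png(f_roc, width = 700, height = 500)
  graphics::plot(rates$threshold, rates$far, type = "l", col = "red",
                 xlab = "score threshold", ylab = "rate", ylim = c(0, 1),
                 main = sprintf("FAR / FRR (EER = %.2f%%)", 100 * eer))
  graphics::lines(rates$threshold, rates$frr, col = "blue")
  graphics::legend("right", col = c("red", "blue"), lty = 1,
                   legend = c("FAR", "FRR"), bty = "n")
  grDevices::dev.off()
  summary <- list(
    eer = eer,
    n_genuine = nrow(g), n_imposter = nrow(i),
    genuine_score = list(min = min(g$s), median = stats::median(g$s),
                         max = max(g$s)),
    imposter_score = list(min = min(i$s), median = stats::median(i$s),
                          max = max(i$s)),
    normalizer = list(dmin = scores$normalizer$dmin,
                      dmax = scores$normalizer$dmax),
    rate_table = rates)
  jsonlite::write_json(summary, f_sum, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(c(f_scores, f_rates, f_hist, f_roc, f_sum))
}
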