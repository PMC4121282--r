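#' Registration settings
#'
#' @param fwhm_mm Gaussian pre-smoothing applied to both volumes before
#'   optimisation, mm (default 5).
#' @param tol relative SSD decrease below which iteration stops.
#' @param max_iter maximum number of Gauss-Newton iterations.
#' @param mask optional logical array on the template grid restricting the
#'   SSD; `NULL` evaluates the whole grid.
#' @return A list of settings for [estimate_rigid()].
#' @export
registration_settings <- function(fwhm_mm = 5, tol = 1e-6, max_iter = 32L,
                                  mask = NULL) {
  stopifnot(fwhm_mm >= 0, tol > 0, max_iter >= 1)
  list(fwhm_mm = fwhm_mm, tol = tol, max_iter = as.integer(max_iter),
       mask = mask)
}

#' Rigid registration of an image to a template
#'
#' Estimates the 6-parameter rigid transform `M` mapping image world
#' coordinates onto template world coordinates by minimising the sum of
#' squared intensity differences between the transformed image and the
#' template. Both volumes are pre-smoothed with a Gaussian kernel (default
#' 5 mm FWHM) to convexify the cost around the basin. Each iteration
#' linearises the residual (first-order Taylor expansion in the six
#' parameters; the Jacobian is the analytic chain of the image intensity
#' gradient with the transform derivatives) and takes a Gauss-Newton step
#' with Levenberg-Marquardt damping escalated whenever the SSD would
#' increase.
#'
#' @param image moving [brain_volume].
#' @param template fixed [brain_volume]; the SSD is evaluated on its grid.
#' @param cfg settings from [registration_settings()].
#' @param init optional length-6 starting parameters.
#' @return An object of class `registration_result`: `params` (named
#'   6-vector, rotations wrapped to `(-pi, pi]`), `matrix` (4x4,
#'   image-to-template), `ssd_trace` (accepted SSD per iteration,
#'   non-increasing), `converged`, `n_iter`.
#' @export
estimate_rigid <- function(image, template, cfg = registration_settings(),
                           init = rep(0, 6)) {
  stopifnot(inherits(image, "brain_volume"), inherits(template, "brain_volume"))
  im <- gaussian_smooth(image, cfg$fwhm_mm)
  tm <- gaussian_smooth(template, cfg$fwhm_mm)
  tdat <- as.numeric(tm$data)
  sel <- if (is.null(cfg$mask)) TRUE else as.logical(cfg$mask)

  aim_inv <- solve(im$affine)
  a3inv <- solve(im$affine[1:3, 1:3])
  # residual vector on the template grid for parameter vector p; template
  # voxels whose pulled-back sample falls outside the image are excluded
  # (zero residual) so the field-of-view rim does not penalise motion
  resid <- function(p) {
    M <- build_rigid_matrix(p)
    C <- aim_inv %*% solve(M) %*% tm$affine
    w <- cpp_resample(as.numeric(im$data), dim(im$data), C,
                      dim(tm$data), 0L, fill = NA_real_)
    r <- w - tdat
    r[is.na(r)] <- 0
    r[sel]
  }
  # central-difference voxel gradients of the smoothed image, for the
  # analytic Jacobian of the linearised SSD
  vox_grad <- function(a, axis) {
    dm <- dim(a); L <- dm[axis]
    idx_hi <- pmin(seq_len(L) + 1L, L)
    idx_lo <- pmax(seq_len(L) - 1L, 1L)
    slice <- function(idx) {
      args <- list(a, 1:dm[1], 1:dm[2], 1:dm[3])
      args[[axis + 1L]] <- idx
      do.call(`[`, args)
    }
    (slice(idx_hi) - slice(idx_lo)) / (idx_hi - idx_lo)
  }
  gvox <- lapply(1:3, function(ax) as.numeric(vox_grad(im$data, ax)))
  X <- grid_world(dim(tm$data), tm$affine)  # template voxel world coords
  # residual and analytic Jacobian d r / d p
  resid_jac <- function(p) {
    M <- build_rigid_matrix(p)
    Minv <- solve(M)
    C <- aim_inv %*% Minv %*% tm$affine
    w <- cpp_resample(as.numeric(im$data), dim(im$data), C,
                      dim(tm$data), 0L, fill = NA_real_)
    inb <- !is.na(w)
    r <- w - tdat
    r[!inb] <- 0
    gw <- vapply(1:3, function(ax)
      cpp_resample(gvox[[ax]], dim(im$data), C, dim(tm$data), 0L),
      numeric(length(w)))
    gw <- gw %*% a3inv          # world-mm intensity gradient at sample points
    gw[!inb, ] <- 0
    Y <- X %*% t(Minv[1:3, 1:3]) +
      matrix(Minv[1:3, 4], nrow(X), 3, byrow = TRUE)
    dM <- rigid_matrix_derivs(p)
    J <- matrix(0, length(w), 6L)
    for (j in 1:6) {
      Dj <- -(Minv %*% dM[[j]])
      dy <- Y %*% t(Dj[1:3, 1:3]) +
        matrix(Dj[1:3, 4], nrow(X), 3, byrow = TRUE)
      J[, j] <- rowSums(gw * dy)
    }
    list(r = r[sel], J = J[sel, , drop = FALSE])
  }

  # initial overlap check: fraction of template voxels landing inside image
  M0 <- build_rigid_matrix(init)
  C0 <- solve(im$affine) %*% solve(M0) %*% tm$affine
  probe <- cpp_resample(array(1, dim(im$data)), dim(im$data), C0,
                        dim(tm$data), 1L)
  if (mean(probe > 0) < 0.01)
    stop("no overlap between image and template at initialization")

  p <- as.numeric(init)
  r <- resid(p)
  ssd <- sum(r^2)
  trace <- ssd
  converged <- FALSE
  iter <- 0L
  lambda <- 1e-3  # Levenberg-Marquardt damping of the Gauss-Newton step
  while (iter < cfg$max_iter) {
    iter <- iter + 1L
    if (ssd < 1e-12) { converged <- TRUE; break }
    rj <- resid_jac(p)
    r <- rj$r
    J <- rj$J
    JtJ <- crossprod(J)
    g <- crossprod(J, r)
    dg <- pmax(diag(JtJ), 1e-12)
    accepted <- FALSE
    for (h in 1:12) {
      step <- tryCatch(solve(JtJ + lambda * diag(dg), -g),
                       error = function(e) NULL)
      # trust region: over-long steps hop between basins; force more damping
      if (!is.null(step) &&
          (max(abs(step[1:3])) > 8 || max(abs(step[4:6])) > 0.15))
        step <- NULL
      if (!is.null(step)) {
        pn <- p + as.numeric(step)
        rn <- resid(pn)
        ssdn <- sum(rn^2)
        if (ssdn < ssd) { accepted <- TRUE; break }
      }
      lambda <- lambda * 9
    }
    if (!accepted) {
      # damping exhausted without any decrease: numerically stationary
      converged <- TRUE
      break
    }
    lambda <- max(lambda / 3, 1e-10)
    rel <- (ssd - ssdn) / ssd
    p <- pn; r <- rn; ssd <- ssdn
    trace <- c(trace, ssd)
    if (rel < cfg$tol) { converged <- TRUE; break }
  }
  p[4:6] <- ((p[4:6] + pi) %% (2 * pi)) - pi
  p[4:6][p[4:6] <= -pi] <- p[4:6][p[4:6] <= -pi] + 2 * pi
  names(p) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  structure(list(params = p, matrix = build_rigid_matrix(p),
                 ssd_trace = trace, converged = converged, n_iter = iter),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat("registration_result: t = (",
      paste(signif(x$params[1:3], 4), collapse = ", "), ") mm, r = (",
      paste(signif(x$params[4:6] * 180 / pi, 4), collapse = ", "),
      ") deg\n  ", x$n_iter, "iterations,",
      if (x$converged) "converged" else "NOT converged",
      ", final SSD", signif(utils::tail(x$ssd_trace, 1), 6), "\n")
  invisible(x)
}

#' Save / load a rigid transform as JSON
#'
#' @param result a `registration_result` (or a list with `params` and
#'   `matrix`).
#' @param path JSON file path.
#' @param fixed,moving optional identifiers recorded in the file.
#' @return `path` invisibly; `load_transform()` returns a list with
#'   `params` and `matrix`.
#' @export
save_transform <- function(result, path, fixed = "template", moving = "image") {
  obj <- list(params = as.numeric(result$params),
              matrix = as.numeric(t(result$matrix)),
              fixed = fixed, moving = moving)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_transform
#' @export
load_transform <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(params = as.numeric(obj$params),
       matrix = matrix(as.numeric(obj$matrix), 4, 4, byrow = TRUE),
       fixed = obj$fixed, moving = obj$moving)
}
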