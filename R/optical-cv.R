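# Strict box filter: a cell keeps a value only when its full (2h+1)^2
# window is inside the map and fully defined, so a locally planar map stays
# exactly planar (a symmetric mean of a linear field is the field). The
# usable interior shrinks by h on each side in exchange for jitter
# suppression.
box_smooth_na <- function(m, h) {
  nr <- nrow(m)
  nc <- ncol(m)
  out <- matrix(NA_real_, nr, nc)
  for (i in seq(h + 1L, nr - h)) {
    for (j in seq(h + 1L, nc - h)) {
      blk <- m[(i - h):(i + h), (j - h):(j + h)]
      if (anyNA(blk)) next
      out[i, j] <- mean(blk)
    }
  }
  out
}

# Conduction velocity estimation from an activation map.
#
# local_plane: fit T(x, y) = a*x + b*y + c by least squares in a k x k
# neighbourhood around every interior pixel; the local speed is 1/|grad T|
# (ms/mm -> cm/s). This is the standard activation-gradient estimator for
# uniformly sampled maps. radial_fit: regress activation time on Euclidean
# distance from the stimulus; speed is the reciprocal slope, appropriate for
# point stimulation with radial spread.

#' Estimate conduction velocity from an activation map
#'
#' @param map An `activation_map`.
#' @param method `"local_plane"` (default) or `"radial_fit"` (requires a
#'   stimulus location, either in the map or via `stim`).
#' @param k Neighbourhood size for the local plane fit (odd, default 3).
#'   Coarsely sampled acquisitions benefit from larger windows (see the
#'   methods vignette).
#' @param stim Stimulus pixel `c(row, col)`; overrides the map's.
#' @param exclude_radius Pixels within this many pixel widths of the stimulus
#'   are excluded from averaging (electrode artifact / near-field wavefront
#'   curvature), default 1.5.
#' @param min_grad Gradient magnitudes below this (ms/mm) are treated as
#'   unresolvable (near-simultaneous activation) and excluded.
#' @param presmooth Half-width (pixels) of a box filter applied to the
#'   activation map before the plane fits (0 disables). Noisy activation
#'   times bias `1/|grad T|` upward by convexity; pre-smoothing suppresses
#'   the jitter while leaving any locally planar map exactly unchanged.
#' @return A `cv_result`: `mean_cv` (cm/s), `speed` (per-pixel cm/s image,
#'   `NA` where excluded), `direction` (list of unit-vector component
#'   images `ux`, `uy`), `method`, `n_used`.
#' @export
conduction_velocity <- function(map, method = c("local_plane", "radial_fit"),
                                k = 3L, stim = NULL, exclude_radius = 1.5,
                                min_grad = 1e-6, presmooth = 0L) {
  method <- match.arg(method)
  stopifnot(inherits(map, "activation_map"))
  if (is.null(stim)) stim <- map$stim
  act <- map$act
  nr <- nrow(act)
  nc <- ncol(act)
  px <- map$pixel_size
  if (presmooth > 0L) act <- box_smooth_na(act, as.integer(presmooth))

  excl <- matrix(FALSE, nr, nc)
  if (!is.null(stim)) {
    rr <- matrix(seq_len(nr), nr, nc)
    cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    excl <- sqrt((rr - stim[1L])^2 + (cc - stim[2L])^2) <= exclude_radius
  }

  if (method == "radial_fit") {
    if (is.null(stim)) stopf("radial_fit requires a stimulus location")
    rr <- matrix(seq_len(nr), nr, nc)
    cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    d_mm <- sqrt((rr - stim[1L])^2 + (cc - stim[2L])^2) * px
    use <- !is.na(act) & !excl
    if (sum(use) < 3L) stopf("no resolvable propagation")
    fit <- stats::lm.fit(cbind(1, d_mm[use]), act[use])
    slope <- unname(fit$coefficients[2L])  # ms/mm
    if (!is.finite(slope) || slope < min_grad) {
      stopf("no resolvable propagation")
    }
    speed <- MM_PER_MS_TO_CM_PER_S / slope
    return(structure(
      list(mean_cv = speed, speed = NULL, direction = NULL,
           method = method, n_used = sum(use)),
      class = "cv_result"))
  }

  k <- as.integer(k)
  if (k < 3L || k %% 2L == 0L) stopf("`k` must be an odd integer >= 3")
  half <- k %/% 2L
  if (nr < k || nc < k) stopf("map smaller than the %d x %d neighbourhood", k, k)
  off <- seq(-half, half)
  xo <- rep(off, each = k) * px   # column offsets -> x (mm)
  yo <- rep(off, times = k) * px  # row offsets -> y (mm)
  X <- cbind(x = xo, y = yo, one = 1)
  XtXi <- solve(crossprod(X))
  H <- XtXi %*% t(X)  # 3 x k^2 projector onto (a, b, c)

  speed <- matrix(NA_real_, nr, nc)
  ux <- matrix(NA_real_, nr, nc)
  uy <- matrix(NA_real_, nr, nc)
  any_neighborhood <- FALSE
  for (i in seq(half + 1L, nr - half)) {
    for (j in seq(half + 1L, nc - half)) {
      block <- act[(i - half):(i + half), (j - half):(j + half)]
      vals <- as.vector(block)  # column-major: row (y) fastest, matching xo/yo
      if (anyNA(vals)) next
      any_neighborhood <- TRUE
      if (excl[i, j]) next
      ab <- H %*% vals
      g <- sqrt(ab[1L]^2 + ab[2L]^2)  # |grad T| in ms/mm
      if (g < min_grad) next          # near-simultaneous activation
      speed[i, j] <- MM_PER_MS_TO_CM_PER_S / g
      ux[i, j] <- ab[1L] / g
      uy[i, j] <- ab[2L] / g
    }
  }
  used <- !is.na(speed)
  if (!any(used)) {
    if (any_neighborhood) stopf("no resolvable propagation")
    stopf("no %d x %d fully-defined neighbourhood in the map", k, k)
  }
  structure(
    list(mean_cv = mean(speed[used]), speed = speed,
         direction = list(ux = ux, uy = uy),
         method = method, k = k, n_used = sum(used)),
    class = "cv_result")
}

#' Recommended CV analysis settings per acquisition geometry
#'
#' The photodiode array (1 mm, 1.2 kHz) oversamples the upstroke in time, so
#' a short temporal smoothing window plus the default 3 x 3 plane fit is
#' enough. The EMCCD camera (80 um, 125 Hz) undersamples it: temporal
#' smoothing would flatten the upstroke, while activation-time jitter is
#' large relative to the ~0.2 ms/px gradients, so no temporal smoothing, a
#' 7 x 7 plane window and a 5 x 5 activation-map pre-smooth are used
#' instead. Derived a priori from noise propagation (see the methods
#' vignette), not fitted to data.
#'
#' @param geometry `"photodiode"` or `"camera"`.
#' @return List with `smooth_ms`, `k`, `presmooth` for [condition()] /
#'   [conduction_velocity()].
#' @export
cv_analysis_settings <- function(geometry = c("photodiode", "camera")) {
  geometry <- match.arg(geometry)
  if (geometry == "photodiode") {
    list(smooth_ms = 4, k = 3L, presmooth = 0L)
  } else {
    list(smooth_ms = 0, k = 7L, presmooth = 2L)
  }
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s: mean CV %.2f cm/s over %d pixels\n",
              x$method, x$mean_cv, x$n_used))
  invisible(x)
}
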