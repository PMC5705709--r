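# Hyperspectral vascular pipeline: Beer-Lambert absorbance, non-negative
# two-chromophore unmixing into a total-hemoglobin map, contrast-limited
# adaptive histogram equalization, in-ROI thresholding with small-object
# removal, and blood vessel density.

#' Unmix a hyperspectral stack into a total-hemoglobin map
#'
#' Per pixel, absorbance `A(lambda) = -log10(I / I_ref)` is fitted as
#' `A = eps_HbO2 * c1 + eps_Hb * c2 (+ c0)` with `c1, c2 >= 0` (the offset
#' `c0`, when enabled, is unconstrained and absorbs wavelength-flat
#' scattering loss). With at most two sign-constrained coefficients the NNLS
#' solution is found exactly by enumerating active sets, vectorised over all
#' pixels. Total hemoglobin is `c1 + c2`, in relative units (concentration x
#' pathlength); no absolute quantification is claimed.
#'
#' @param stack A [hyperspectral_stack()] with at least 3 wavelengths whose
#'   reference intensities are available (`i_ref`: scalar, per-wavelength, or
#'   full array).
#' @param offset Include the free offset term (default `FALSE`).
#' @param extinction Extinction table; defaults to the packaged asset at the
#'   stack's wavelengths.
#' @return An `hb_map`: `thb`, `c1`, `c2`, `residual` (per-pixel residual
#'   norm), `mask` (pixels with all intensities > 0), `roi`.
#' @export
unmix_hemoglobin <- function(stack, offset = FALSE, extinction = NULL) {
  stopifnot(inherits(stack, "hyperspectral_stack"))
  nl <- length(stack$wavelengths)
  n_unknown <- 2L + as.integer(offset)
  if (nl < max(3L, n_unknown)) {
    stopf("unmixing needs at least %d wavelengths (got %d)",
          max(3L, n_unknown), nl)
  }
  if (is.null(extinction)) extinction <- hb_extinction(stack$wavelengths)
  d <- dim(stack$images)
  npix <- d[2L] * d[3L]
  imat <- matrix(stack$images, nrow = nl, ncol = npix)
  iref <- stack$i_ref
  if (is.array(iref) && length(dim(iref)) == 3L) {
    iref <- matrix(iref, nrow = nl, ncol = npix)
  } else if (length(iref) == 1L) {
    iref <- matrix(iref, nl, npix)
  } else if (length(iref) == nl) {
    iref <- matrix(iref, nl, npix)
  } else {
    stopf("`i_ref` must be a scalar, one value per wavelength, or a full array")
  }
  ok <- colSums(imat <= 0 | iref <= 0) == 0L
  A <- matrix(NA_real_, nl, npix)
  A[, ok] <- -log10(imat[, ok, drop = FALSE] / iref[, ok, drop = FALSE])

  e1 <- extinction$eps_hbo2
  e2 <- extinction$eps_hb
  # candidate active sets: both free, c2 = 0, c1 = 0, both 0
  solve_sub <- function(cols, Amat) {
    # least squares for all pixels at once; returns list(coef, sse)
    if (!length(cols)) {
      fit <- matrix(0, nl, ncol(Amat))
      return(list(coef = NULL, sse = colSums(Amat^2, na.rm = TRUE)))
    }
    X <- do.call(cbind, cols)
    P <- solve(crossprod(X), t(X))
    cf <- P %*% Amat
    res <- Amat - X %*% cf
    list(coef = cf, sse = colSums(res^2))
  }
  base <- if (offset) list(rep(1, nl)) else list()
  subs <- list(
    c(base, list(e1, e2)),
    c(base, list(e1)),
    c(base, list(e2)),
    base
  )
  okA <- A[, ok, drop = FALSE]
  n_ok <- ncol(okA)
  best_sse <- rep(Inf, n_ok)
  best_c1 <- numeric(n_ok)
  best_c2 <- numeric(n_ok)
  off_i <- as.integer(offset)
  for (s in seq_along(subs)) {
    cols <- subs[[s]]
    if (!length(cols) && !offset) {
      sse <- colSums(okA^2)
      c1v <- numeric(n_ok)
      c2v <- numeric(n_ok)
    } else {
      fit <- solve_sub(cols, okA)
      sse <- fit$sse
      c1v <- c2v <- numeric(n_ok)
      if (s == 1L) {
        c1v <- fit$coef[off_i + 1L, ]
        c2v <- fit$coef[off_i + 2L, ]
      } else if (s == 2L) {
        c1v <- fit$coef[off_i + 1L, ]
      } else if (s == 3L) {
        c2v <- fit$coef[off_i + 1L, ]
      }
    }
    feas <- c1v >= 0 & c2v >= 0
    better <- feas & sse < best_sse
    best_sse[better] <- sse[better]
    best_c1[better] <- c1v[better]
    best_c2[better] <- c2v[better]
  }
  c1 <- c2 <- resid <- rep(NA_real_, npix)
  c1[ok] <- best_c1
  c2[ok] <- best_c2
  resid[ok] <- sqrt(best_sse)
  shape <- c(d[2L], d[3L])
  structure(
    list(thb = matrix(c1 + c2, shape[1L], shape[2L]),
         c1 = matrix(c1, shape[1L], shape[2L]),
         c2 = matrix(c2, shape[1L], shape[2L]),
         residual = matrix(resid, shape[1L], shape[2L]),
         mask = matrix(ok, shape[1L], shape[2L]),
         roi = stack$roi, offset = offset),
    class = "hb_map"
  )
}

#' @export
print.hb_map <- function(x, ...) {
  cat(sprintf("<hb_map> %d x %d px | THb range %.3g-%.3g | median residual %.3g\n",
              nrow(x$thb), ncol(x$thb), min(x$thb, na.rm = TRUE),
              max(x$thb, na.rm = TRUE),
              stats::median(x$residual, na.rm = TRUE)))
  invisible(x)
}

#' Contrast-limited adaptive histogram equalization (CLAHE)
#'
#' The image is scaled to `[0, 1]`, divided into a tile grid, and each tile
#' gets a clipped-histogram equalization transfer function; pixel values are
#' mapped through the transfer functions of the (up to) four surrounding
#' tile centers with bilinear weights. `interpolate = FALSE` applies each
#' tile's own transfer function directly (blockier, but exactly
#' rank-preserving within a tile).
#'
#' @param img Numeric matrix, or an `hb_map` (its `thb` image is used, `NA`
#'   treated as the minimum).
#' @param tile_grid `c(nx, ny)` tile counts (default 8 x 8).
#' @param clip_limit Histogram clip limit as a fraction of the tile pixel
#'   count (default 0.01); excess is redistributed uniformly.
#' @param n_bins Histogram bins.
#' @param interpolate Bilinear blending between tile mappings.
#' @return Matrix in `[0, 1]`.
#' @export
enhance_contrast <- function(img, tile_grid = c(8, 8), clip_limit = 0.01,
                             n_bins = 256L, interpolate = TRUE) {
  if (inherits(img, "hb_map")) img <- img$thb
  if (!all(is.finite(img))) img[!is.finite(img)] <- min(img, na.rm = TRUE)
  nr <- nrow(img)
  nc <- ncol(img)
  rng <- range(img)
  if (rng[2L] == rng[1L]) return(matrix(0, nr, nc))
  u <- (img - rng[1L]) / (rng[2L] - rng[1L])
  tiles_r <- ceiling(nr / tile_grid[2L])
  tiles_c <- ceiling(nc / tile_grid[1L])
  if (tiles_r >= nr || tiles_c >= nc) {
    warnf("tile larger than the image; falling back to global equalization")
    cdf <- stats::ecdf(as.vector(u))
    return(matrix(cdf(u), nr, nc))
  }
  ntr <- ceiling(nr / tiles_r)
  ntc <- ceiling(nc / tiles_c)
  bin <- pmin(floor(u * n_bins) + 1L, n_bins)
  # per-tile clipped-CDF lookup tables
  luts <- array(0, dim = c(ntr, ntc, n_bins))
  centers_r <- numeric(ntr)
  centers_c <- numeric(ntc)
  for (ti in seq_len(ntr)) {
    rs <- ((ti - 1L) * tiles_r + 1L):min(ti * tiles_r, nr)
    centers_r[ti] <- mean(rs)
    for (tj in seq_len(ntc)) {
      cs <- ((tj - 1L) * tiles_c + 1L):min(tj * tiles_c, nc)
      if (ti == 1L) centers_c[tj] <- mean(cs)
      h <- tabulate(bin[rs, cs], nbins = n_bins)
      npx <- sum(h)
      lim <- max(1, clip_limit * npx)
      excess <- sum(pmax(h - lim, 0))
      h <- pmin(h, lim) + excess / n_bins
      luts[ti, tj, ] <- cumsum(h) / sum(h)
    }
  }
  if (!interpolate) {
    out <- matrix(0, nr, nc)
    for (ti in seq_len(ntr)) {
      rs <- ((ti - 1L) * tiles_r + 1L):min(ti * tiles_r, nr)
      for (tj in seq_len(ntc)) {
        cs <- ((tj - 1L) * tiles_c + 1L):min(tj * tiles_c, nc)
        out[rs, cs] <- luts[ti, tj, ][bin[rs, cs]]
      }
    }
    return(out)
  }
  # bilinear interpolation between the four surrounding tile mappings
  ri <- matrix(seq_len(nr), nr, nc)
  ci <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  fr <- stats::approx(centers_r, seq_len(ntr), xout = seq_len(nr),
                      rule = 2)$y
  fc <- stats::approx(centers_c, seq_len(ntc), xout = seq_len(nc),
                      rule = 2)$y
  r0 <- pmin(pmax(floor(fr), 1L), ntr)
  c0 <- pmin(pmax(floor(fc), 1L), ntc)
  r1 <- pmin(r0 + 1L, ntr)
  c1 <- pmin(c0 + 1L, ntc)
  wr <- fr - r0
  wc <- fc - c0
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    bi <- bin[i, ]
    l00 <- luts[cbind(r0[i], c0, bi)]
    l01 <- luts[cbind(r0[i], c1, bi)]
    l10 <- luts[cbind(r1[i], c0, bi)]
    l11 <- luts[cbind(r1[i], c1, bi)]
    out[i, ] <- (1 - wr[i]) * ((1 - wc) * l00 + wc * l01) +
      wr[i] * ((1 - wc) * l10 + wc * l11)
  }
  pmin(pmax(out, 0), 1)
}

# Otsu's threshold on a numeric vector (maximize between-class variance)
otsu_threshold <- function(x, n_bins = 256L) {
  rng <- range(x)
  if (rng[2L] == rng[1L]) return(NA_real_)
  edges <- seq(rng[1L], rng[2L], length.out = n_bins + 1L)
  h <- tabulate(pmin(findInterval(x, edges, all.inside = TRUE), n_bins),
                nbins = n_bins)
  w <- h / sum(h)
  mids <- (edges[-1L] + edges[-(n_bins + 1L)]) / 2
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  edges[which.max(sigma_b) + 1L]
}

# 8-connected component labelling (two-pass union-find)
label_components <- function(mask) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  parent <- integer(0)
  find_root <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  nxt <- 0L
  for (j in seq_len(nc)) {
    for (i in seq_len(nr)) {
      if (!mask[i, j]) next
      nb <- integer(0)
      if (i > 1L && mask[i - 1L, j]) nb <- c(nb, labels[i - 1L, j])
      if (j > 1L) {
        if (mask[i, j - 1L]) nb <- c(nb, labels[i, j - 1L])
        if (i > 1L && mask[i - 1L, j - 1L]) nb <- c(nb, labels[i - 1L, j - 1L])
        if (i < nr && mask[i + 1L, j - 1L]) nb <- c(nb, labels[i + 1L, j - 1L])
      }
      if (!length(nb)) {
        nxt <- nxt + 1L
        parent[nxt] <- nxt
        labels[i, j] <- nxt
      } else {
        m <- min(nb)
        labels[i, j] <- m
        for (b in nb) {
          rb <- find_root(b)
          rm <- find_root(m)
          if (rb != rm) parent[max(rb, rm)] <- min(rb, rm)
        }
      }
    }
  }
  if (nxt > 0L) {
    roots <- vapply(seq_len(nxt), find_root, integer(1))
    relab <- match(roots, sort(unique(roots)))
    pos <- labels > 0L
    labels[pos] <- relab[labels[pos]]
  }
  labels
}

#' Segment vessels from an enhanced hemoglobin image
#'
#' The threshold is computed within the ROI only (Otsu by default, or a
#' fixed value), objects smaller than `min_object_px` (8-connectivity) are
#' removed, and the mask is restricted to the ROI.
#'
#' @param img Numeric matrix (typically the [enhance_contrast()] output).
#' @param roi Logical ROI matrix (non-empty); default whole image.
#' @param method `"otsu"` or `"fixed"`.
#' @param threshold Threshold value for `method = "fixed"`.
#' @param min_object_px Minimum connected-object size kept.
#' @return A `vessel_mask`: `mask` (logical), `roi`, `provenance` (threshold
#'   method and parameters). A degenerate (single-valued) ROI histogram
#'   yields an empty mask with a warning.
#' @export
segment_vessels <- function(img, roi = NULL, method = c("otsu", "fixed"),
                            threshold = NULL, min_object_px = 0L) {
  method <- match.arg(method)
  nr <- nrow(img)
  nc <- ncol(img)
  if (is.null(roi)) roi <- matrix(TRUE, nr, nc)
  if (!any(roi)) stopf("ROI is empty")
  vals <- img[roi]
  if (method == "otsu") {
    thr <- otsu_threshold(vals)
    if (is.na(thr)) {
      warnf("degenerate histogram (single value) in ROI: empty mask")
      mask <- matrix(FALSE, nr, nc)
      return(structure(
        list(mask = mask, roi = roi,
             provenance = list(method = method, threshold = NA_real_,
                               min_object_px = min_object_px)),
        class = "vessel_mask"))
    }
  } else {
    if (is.null(threshold)) stopf("method 'fixed' needs a `threshold`")
    thr <- threshold
  }
  mask <- img > thr & roi
  if (min_object_px > 0L && any(mask)) {
    lab <- label_components(mask)
    keep <- which(tabulate(lab[lab > 0L]) >= min_object_px)
    mask <- matrix(lab %in% keep, nr, nc) & mask
  }
  structure(
    list(mask = mask, roi = roi,
         provenance = list(method = method, threshold = thr,
                           min_object_px = min_object_px)),
    class = "vessel_mask"
  )
}

#' Blood vessel density
#'
#' @param mask A `vessel_mask` (or a logical matrix with `roi` supplied).
#' @param roi Logical ROI matrix when `mask` is a plain matrix.
#' @return Vessel pixels / ROI pixels, in `[0, 1]`.
#' @export
bvd <- function(mask, roi = NULL) {
  if (inherits(mask, "vessel_mask")) {
    roi <- mask$roi
    mask <- mask$mask
  }
  if (is.null(roi)) roi <- matrix(TRUE, nrow(mask), ncol(mask))
  if (!any(roi)) stopf("ROI area is zero")
  sum(mask & roi) / sum(roi)
}

#' Fold change between two blood vessel densities
#'
#' @param bvd_t1,bvd_t0 Densities at the later / earlier time point.
#' @return `bvd_t1 / bvd_t0`; `NA` with a warning when `bvd_t0` is 0.
#' @export
bvd_fold_change <- function(bvd_t1, bvd_t0) {
  if (bvd_t0 == 0) {
    warnf("baseline BVD is 0: fold change undefined")
    return(NA_real_)
  }
  bvd_t1 / bvd_t0
}
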