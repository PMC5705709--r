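# GCaMP calcium transient quantification: tiled ROI placement, dF/F
# amplitude per ROI (F_base = lowest-decile mean, F_peak = mean of detected
# transient peaks), and transient event timing/rate.

#' Place square analysis ROIs on a movie
#'
#' ROIs are `round(roi_size_um / pixel_size_um)` pixels on a side. The
#' default placement ranks candidate positions by total temporal signal
#' variance and greedily keeps the highest-scoring non-overlapping ones;
#' ties break in top-left scan order (row, then column), so placement is
#' deterministic on uniform movies.
#'
#' @param stack A [movie_stack()].
#' @param roi_size_um ROI side length in um (default 400, the intravital
#'   analysis region size).
#' @param n_rois Number of ROIs (default 3).
#' @param placement `"variance"` (default) or `"grid"` (evenly spaced along
#'   the image diagonal).
#' @return An `roi_set`: data.frame with `row0`, `col0`, `row1`, `col1`
#'   (1-based inclusive bounds), plus `size_px` and `size_um` attributes.
#' @export
roi_grid <- function(stack, roi_size_um = 400, n_rois = 3L,
                     placement = c("variance", "grid")) {
  placement <- match.arg(placement)
  stopifnot(inherits(stack, "movie_stack"))
  px_um <- stack$pixel_size * 1000
  size <- max(1L, round(roi_size_um / px_um))
  d <- dim(stack$frames)
  nr <- d[2L]
  nc <- d[3L]
  if (size > nr || size > nc) {
    stopf("a %d px ROI does not fit a %d x %d image", size, nr, nc)
  }
  if (placement == "grid") {
    n_fit_r <- nr %/% size
    n_fit_c <- nc %/% size
    if (n_fit_r * n_fit_c < n_rois) {
      stopf("cannot place %d non-overlapping ROIs of %d px", n_rois, size)
    }
    anchors <- expand.grid(
      row0 = 1L + size * (seq_len(n_fit_r) - 1L),
      col0 = 1L + size * (seq_len(n_fit_c) - 1L))
    anchors <- anchors[seq_len(n_rois), , drop = FALSE]
  } else {
    pm <- pixel_matrix(stack)
    v <- matrix(apply(pm, 2L, stats::var), nr, nc)
    # integral image for box sums of variance; ii[i+1, j+1] = sum up to (i, j)
    cs <- t(apply(apply(v, 2L, cumsum), 1L, cumsum))
    ii <- matrix(0, nr + 1L, nc + 1L)
    ii[-1L, -1L] <- cs
    score <- function(r0, c0) {
      ii[r0 + size, c0 + size] - ii[r0, c0 + size] -
        ii[r0 + size, c0] + ii[r0, c0]
    }
    cand <- expand.grid(row0 = seq_len(nr - size + 1L),
                        col0 = seq_len(nc - size + 1L))
    cand$score <- mapply(score, cand$row0, cand$col0)
    # quantize so float noise in the cumulative sums cannot defeat the
    # top-left tie-break on uniform movies
    tol <- 1e-9 * max(abs(cand$score), 1)
    cand$score <- round(cand$score / tol) * tol
    cand <- cand[order(-cand$score, cand$row0, cand$col0), , drop = FALSE]
    picked <- list()
    for (i in seq_len(nrow(cand))) {
      r0 <- cand$row0[i]
      c0 <- cand$col0[i]
      clash <- any(vapply(picked, function(p) {
        r0 <= p$row0 + size - 1L && p$row0 <= r0 + size - 1L &&
          c0 <= p$col0 + size - 1L && p$col0 <= c0 + size - 1L
      }, logical(1)))
      if (!clash) picked[[length(picked) + 1L]] <- list(row0 = r0, col0 = c0)
      if (length(picked) == n_rois) break
    }
    if (length(picked) < n_rois) {
      stopf("cannot place %d non-overlapping ROIs of %d px", n_rois, size)
    }
    anchors <- do.call(rbind, lapply(picked, as.data.frame))
  }
  out <- data.frame(
    row0 = anchors$row0, col0 = anchors$col0,
    row1 = anchors$row0 + size - 1L, col1 = anchors$col0 + size - 1L)
  structure(out, size_px = size, size_um = size * px_um, class =
              c("roi_set", "data.frame"))
}

#' Calcium transient amplitude dF/F of a fluorescence trace
#'
#' `dF/F = (F_peak - F_base) / F_base` with `F_base` the mean of the
#' lowest-decile samples (or the mean over a pre-event window when event
#' times are supplied) and `F_peak` the mean of all detected transient peak
#' values (averaging across transients rather than taking the single
#' maximum, for robustness).
#'
#' @param trace Numeric fluorescence trace (>= 10 samples).
#' @param prominence_frac Peak prominence threshold as a fraction of the
#'   trace range.
#' @param base_window Optional index range `c(i0, i1)` for a pre-event
#'   baseline instead of the lowest-decile rule.
#' @param min_range Traces whose range is below `min_range * |F_base|` are
#'   declared transient-free.
#' @return List: `dff`, `f_base`, `f_peak`, `n_transients`,
#'   `no_transients` flag (`dff = 0` when nothing is detected).
#' @export
dff_amplitude <- function(trace, prominence_frac = 0.5, base_window = NULL,
                          min_range = 1e-3) {
  if (length(trace) < 10L) stopf("trace needs at least 10 samples")
  if (is.null(base_window)) {
    srt <- sort(trace)
    f_base <- mean(srt[seq_len(max(1L, ceiling(length(trace) / 10)))])
  } else {
    f_base <- mean(trace[base_window[1L]:base_window[2L]])
  }
  if (f_base <= 0) stopf("F_base must be > 0 (got %g)", f_base)
  rng <- max(trace) - min(trace)
  if (rng < min_range * abs(f_base)) {
    return(list(dff = 0, f_base = f_base, f_peak = f_base,
                n_transients = 0L, no_transients = TRUE))
  }
  pk <- find_peaks(trace, prominence = prominence_frac * rng)
  if (!length(pk)) {
    return(list(dff = 0, f_base = f_base, f_peak = f_base,
                n_transients = 0L, no_transients = TRUE))
  }
  f_peak <- mean(trace[pk])
  list(dff = (f_peak - f_base) / f_base, f_base = f_base, f_peak = f_peak,
       n_transients = length(pk), no_transients = FALSE)
}

#' Movie-level dF/F over tiled ROIs
#'
#' @param stack A calcium [movie_stack()].
#' @param rois An `roi_set` (default: [roi_grid()] with its defaults).
#' @param ... Passed to [dff_amplitude()].
#' @return A `ca_metrics` list: `per_roi` (data.frame of per-ROI dF/F),
#'   `mean_dff`, `rois`.
#' @export
dff_movie <- function(stack, rois = NULL, ...) {
  if (is.null(rois)) rois <- roi_grid(stack)
  per <- lapply(seq_len(nrow(rois)), function(i) {
    tr <- roi_trace(stack, as.numeric(rois[i, c("row0", "col0", "row1", "col1")]))
    dff_amplitude(tr, ...)
  })
  per_roi <- data.frame(
    roi = seq_len(nrow(rois)),
    dff = vapply(per, `[[`, numeric(1), "dff"),
    f_base = vapply(per, `[[`, numeric(1), "f_base"),
    n_transients = vapply(per, `[[`, integer(1), "n_transients"))
  structure(
    list(per_roi = per_roi, mean_dff = mean(per_roi$dff), rois = rois),
    class = "ca_metrics")
}

#' Detect calcium transient events and firing rate
#'
#' @param trace Numeric fluorescence trace.
#' @param dt Sample interval in ms.
#' @param prominence Absolute prominence threshold; default half the trace
#'   range.
#' @return List: `times_ms` (peak times), `n`, `rate_per_min`.
#' @export
transient_events <- function(trace, dt, prominence = NULL) {
  rng <- max(trace) - min(trace)
  if (is.null(prominence)) prominence <- 0.5 * rng
  pk <- if (rng > 0) find_peaks(trace, prominence = prominence) else integer(0)
  dur_ms <- (length(trace) - 1L) * dt
  list(times_ms = (pk - 1L) * dt, n = length(pk),
       rate_per_min = if (dur_ms > 0) length(pk) / dur_ms * 60000 else 0)
}
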