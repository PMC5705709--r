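# Signal conditioning ahead of activation/APD analysis: optional per-pixel
# linear detrend, temporal low-pass (centered moving average), robust
# percentile normalization to [0, 1], and SNR-based mask pruning. All steps
# are affine-equivariant, so gain/offset changes in the raw fluorescence do
# not change any downstream measurement.

#' Condition a fluorescence movie
#'
#' @param stack A [movie_stack()].
#' @param detrend Remove a per-pixel linear trend first.
#' @param smooth_ms Temporal moving-average window in ms (0 disables; the
#'   window is rounded to an odd number of samples).
#' @param normalize_quantiles Robust min/max percentiles used for the
#'   per-pixel normalization (default 2nd/98th), preferred over raw min/max
#'   for robustness to single-frame noise spikes. Output is clipped to
#'   `[0, 1]`.
#' @param snr_min Pixels whose raw peak-to-peak (robust) amplitude is below
#'   `snr_min` times the per-pixel noise estimate (SD of first differences /
#'   sqrt(2)) are removed from the mask.
#' @return A conditioned `movie_stack` (attribute `conditioned = TRUE`), with
#'   low-SNR pixels dropped from the mask.
#' @export
condition <- function(stack, detrend = FALSE, smooth_ms = 0,
                      normalize_quantiles = c(0.02, 0.98), snr_min = 8) {
  stopifnot(inherits(stack, "movie_stack"))
  pm <- pixel_matrix(stack)
  nt <- nrow(pm)
  if (detrend) pm <- apply(pm, 2L, detrend_linear)
  if (smooth_ms > 0) {
    width <- max(1L, round(smooth_ms / stack$dt))
    pm <- apply(pm, 2L, moving_average, width = width)
  }
  lo <- apply(pm, 2L, stats::quantile, probs = normalize_quantiles[1L],
              names = FALSE)
  hi <- apply(pm, 2L, stats::quantile, probs = normalize_quantiles[2L],
              names = FALSE)
  amp <- hi - lo
  noise <- apply(pm, 2L, function(v) stats::sd(diff(v)) / sqrt(2))
  good <- amp > 0 & (noise == 0 | amp / pmax(noise, .Machine$double.eps) >= snr_min)
  mask <- stack$mask & matrix(good, nrow(stack$mask), ncol(stack$mask))
  if (!any(mask)) {
    stopf("all pixels fell below the SNR threshold (snr_min = %g)", snr_min)
  }
  amp[amp == 0] <- 1  # dead pixels are masked anyway; avoid 0/0
  norm <- sweep(sweep(pm, 2L, lo, `-`), 2L, amp, `/`)
  norm <- pmin(pmax(norm, 0), 1)
  out <- stack
  out$frames <- array(norm, dim(stack$frames))
  out$mask <- mask
  attr(out, "conditioned") <- TRUE
  attr(out, "conditioning") <- list(
    detrend = detrend, smooth_ms = smooth_ms,
    normalize_quantiles = normalize_quantiles, snr_min = snr_min)
  out
}
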