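# Action potential duration at a configurable repolarization level
# (default 80%): per pixel, time from activation to the first downward
# crossing of (1 - level) of the normalized amplitude after the peak.

#' Compute an APD map
#'
#' @param stack The conditioned [movie_stack()] the activation map came from.
#' @param map The matching `activation_map`.
#' @param level Repolarization fraction in (0, 1); 0.8 gives APD80, i.e. the
#'   downward crossing of 20% of normalized amplitude.
#' @return An `apd_map`: `apd` (matrix, ms; `NA` where activation is
#'   undefined or repolarization never reaches the level within the record),
#'   `level`, `median_apd`.
#' @export
apd_map <- function(stack, map, level = 0.8) {
  stopifnot(inherits(stack, "movie_stack"), inherits(map, "activation_map"))
  if (level <= 0 || level >= 1) stopf("`level` must be in (0, 1)")
  if (!isTRUE(attr(stack, "conditioned"))) stack <- condition(stack)
  pm <- pixel_matrix(stack)
  t <- frame_times(stack)
  thr <- 1 - level
  act_v <- as.vector(map$act)
  apd <- rep(NA_real_, length(act_v))
  for (j in which(!is.na(act_v))) {
    v <- pm[, j]
    a <- act_v[j]
    idx <- which(t >= a)
    if (length(idx) < 2L) next
    pk <- idx[which.max(v[idx])]
    tc <- cross_time(t, v, thr, "down", which_cross = "first", after = t[pk])
    if (!is.na(tc)) apd[j] <- tc - a
  }
  apd <- matrix(apd, nrow(map$act), ncol(map$act))
  structure(
    list(apd = apd, level = level,
         median_apd = stats::median(apd, na.rm = TRUE)),
    class = "apd_map"
  )
}

#' @export
print.apd_map <- function(x, ...) {
  cat(sprintf("<apd_map> APD%d: median %.1f ms (%d px defined)\n",
              round(100 * x$level), x$median_apd, sum(!is.na(x$apd))))
  invisible(x)
}
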