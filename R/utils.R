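# Shared numerical helpers: seeded RNG scoping, peak finding, threshold
# crossings, moving averages. Times in ms unless a _s suffix says otherwise;
# lengths in mm (um where conventional); forces in mN; speeds in cm/s.

# 1 mm/ms == 100 cm/s
MM_PER_MS_TO_CM_PER_S <- 100

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `code` with the global random-number state set from `seed`, then
#' restores the previous state, so generators are reproducible without
#' leaking global side effects.
#'
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

check_number <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stopf("`%s` must be a single finite number", name)
  }
  if (strict && x <= lower) stopf("`%s` must be > %g", name, lower)
  if (!strict && x < lower) stopf("`%s` must be >= %g", name, lower)
  invisible(x)
}

#' Find local maxima of a numeric trace
#'
#' Plateau-tolerant peak detection with topographic prominence, the same
#' notion used by standard signal-processing toolkits: a peak's prominence
#' is its height above the higher of the two valley floors separating it
#' from taller terrain.
#'
#' @param x Numeric vector.
#' @param prominence Minimum prominence to keep a peak (same units as `x`).
#' @param min_distance Minimum index separation between kept peaks; when two
#'   peaks are closer, the smaller one is dropped.
#' @return Integer vector of peak indices (first sample of a plateau).
#' @export
find_peaks <- function(x, prominence = 0, min_distance = 1L) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  # collapse exact plateaus so a flat-topped peak yields one index
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  v <- r$values
  m <- length(v)
  if (m < 3L) return(integer(0))
  cand <- which(v[2:(m - 1L)] > v[1:(m - 2L)] & v[2:(m - 1L)] > v[3:m]) + 1L
  if (!length(cand)) return(integer(0))
  idx <- starts[cand]
  prom <- vapply(cand, function(j) {
    pk <- v[j]
    lmin <- pk
    for (i in seq(j - 1L, 1L)) {
      if (v[i] > pk) break
      lmin <- min(lmin, v[i])
    }
    rmin <- pk
    for (i in seq(j + 1L, m)) {
      if (v[i] > pk) break
      rmin <- min(rmin, v[i])
    }
    pk - max(lmin, rmin)
  }, numeric(1))
  keep <- prom >= prominence
  idx <- idx[keep]
  prom <- prom[keep]
  if (min_distance > 1L && length(idx) > 1L) {
    ord <- order(-prom, idx)
    sel <- logical(length(idx))
    taken <- integer(0)
    for (i in ord) {
      if (!length(taken) || all(abs(idx[i] - taken) >= min_distance)) {
        sel[i] <- TRUE
        taken <- c(taken, idx[i])
      }
    }
    idx <- sort(idx[sel])
  }
  idx
}

#' Sub-sample threshold crossing time by linear interpolation
#'
#' @param t Time vector (strictly increasing).
#' @param v Value vector.
#' @param level Threshold.
#' @param direction `"up"` (crossing from below) or `"down"`.
#' @param which_cross `"first"` or `"last"` matching crossing.
#' @param after,before Restrict the search to `t >= after` / `t <= before`.
#' @return Interpolated crossing time, or `NA_real_` when none exists. Exact
#'   touches (a sample equal to `level`) resolve to the earliest such sample.
#' @export
cross_time <- function(t, v, level, direction = c("up", "down"),
                       which_cross = c("first", "last"),
                       after = -Inf, before = Inf) {
  direction <- match.arg(direction)
  which_cross <- match.arg(which_cross)
  sel <- which(t >= after & t <= before)
  if (length(sel) < 2L) return(NA_real_)
  t <- t[sel]
  v <- v[sel]
  n <- length(v)
  a <- v[-n]
  b <- v[-1L]
  if (direction == "up") {
    hit <- which(a < level & b >= level)
  } else {
    hit <- which(a > level & b <= level)
  }
  # Flat segments sitting exactly at the level: the bracketing rule above
  # interpolates onto the first at-level sample, i.e. ties resolve early.
  # A trace that *starts* at the level counts as already crossed.
  if (!length(hit)) {
    if (v[1L] == level) return(t[1L])
    return(NA_real_)
  }
  k <- if (which_cross == "first") hit[1L] else hit[length(hit)]
  if (b[k] == a[k]) return(t[k])
  frac <- (level - a[k]) / (b[k] - a[k])
  t[k] + frac * (t[k + 1L] - t[k])
}

# centered moving average; width forced odd; edges use shrinking windows
moving_average <- function(x, width) {
  width <- as.integer(width)
  if (width <= 1L) return(x)
  if (width %% 2L == 0L) width <- width + 1L
  n <- length(x)
  half <- width %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# linear detrend against sample index
detrend_linear <- function(x) {
  n <- length(x)
  i <- seq_len(n) - (n + 1) / 2
  x - i * (sum(i * x) / sum(i * i))
}
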