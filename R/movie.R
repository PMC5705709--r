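# MovieStack: the substrate for all optical-mapping and calcium analyses.
# Frames are stored [t, row, col], 0-based in time (frame k is at (k-1)*dt ms
# from recording start); the physical origin sits at the upper-left pixel
# center, x increasing with column, y with row.

#' Construct a fluorescence movie stack
#'
#' @param frames 3-D numeric array `[time, row, col]` of fluorescence values
#'   (arbitrary units), at least 2 frames.
#' @param dt Sampling interval in ms (> 0).
#' @param pixel_size Pixel size in mm (> 0).
#' @param channel `"voltage"` or `"calcium"`.
#' @param mask Logical matrix of valid pixels (`rows x cols`); defaults to all
#'   valid.
#' @return A `movie_stack` object.
#' @export
movie_stack <- function(frames, dt, pixel_size,
                        channel = c("voltage", "calcium"), mask = NULL) {
  channel <- match.arg(channel)
  if (!is.array(frames) || length(dim(frames)) != 3L) {
    stopf("`frames` must be a 3-D array [time, row, col]")
  }
  if (dim(frames)[1L] < 2L) stopf("a movie needs at least 2 frames")
  check_number(dt, "dt", 0, strict = TRUE)
  check_number(pixel_size, "pixel_size", 0, strict = TRUE)
  nr <- dim(frames)[2L]
  nc <- dim(frames)[3L]
  if (is.null(mask)) mask <- matrix(TRUE, nr, nc)
  if (!is.logical(mask) || !identical(dim(mask), c(nr, nc))) {
    stopf("`mask` must be a logical %d x %d matrix matching the frames", nr, nc)
  }
  structure(
    list(frames = frames, dt = dt, pixel_size = pixel_size,
         channel = channel, mask = mask),
    class = "movie_stack"
  )
}

#' @export
print.movie_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<movie_stack> %d frames of %d x %d px | dt = %g ms (%.4g Hz) | %g mm/px | %s | %d/%d valid px\n",
    d[1], d[2], d[3], x$dt, 1000 / x$dt, x$pixel_size, x$channel,
    sum(x$mask), length(x$mask)
  ))
  invisible(x)
}

#' @export
dim.movie_stack <- function(x) dim(x$frames)

# frame times in ms
frame_times <- function(stack) (seq_len(dim(stack$frames)[1L]) - 1L) * stack$dt

# pixel traces as an n_t x n_pix matrix, pixels in column-major (row fastest)
# order matching as.vector(mask)
pixel_matrix <- function(stack) {
  d <- dim(stack$frames)
  matrix(stack$frames, nrow = d[1L], ncol = d[2L] * d[3L])
}

#' Extract the mean trace of a rectangular region
#'
#' @param stack A `movie_stack`.
#' @param roi Integer vector `c(row0, col0, row1, col1)` (1-based, inclusive);
#'   `NULL` averages the whole masked image.
#' @return Numeric vector, one value per frame.
#' @export
roi_trace <- function(stack, roi = NULL) {
  d <- dim(stack$frames)
  if (is.null(roi)) {
    sel <- stack$mask
  } else {
    sel <- matrix(FALSE, d[2L], d[3L])
    sel[roi[1L]:roi[3L], roi[2L]:roi[4L]] <- TRUE
    sel <- sel & stack$mask
  }
  if (!any(sel)) stopf("ROI contains no valid pixels")
  pm <- pixel_matrix(stack)
  rowMeans(pm[, as.vector(sel), drop = FALSE])
}
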