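# File formats: movies and hyperspectral stacks as plain CSV matrices with a
# JSON sidecar carrying the physical metadata (sampling interval, pixel
# size, channel, mask); traces as two-column CSV; run configuration as YAML
# or JSON. Metadata is never silently defaulted: a sidecar missing dt or
# pixel size is an error.

movie_sidecar_path <- function(path) sub("\\.csv$", ".json", path)

#' Write a movie stack to CSV + JSON sidecar
#'
#' The CSV holds one row per frame (column `frame`, then one column per
#' pixel named `r<row>c<col>`, row-fastest order); the sidecar holds
#' `dt_ms`, `pixel_size_mm`, `channel`, `rows`, `cols` and the validity
#' mask.
#'
#' @param stack A [movie_stack()].
#' @param path Output CSV path; the sidecar goes to the same path with a
#'   `.json` extension.
#' @return Invisibly, `c(csv = path, sidecar = <json path>)`.
#' @export
write_movie <- function(stack, path) {
  stopifnot(inherits(stack, "movie_stack"))
  d <- dim(stack$frames)
  pm <- pixel_matrix(stack)
  cn <- as.vector(outer(seq_len(d[2L]), seq_len(d[3L]),
                        function(r, c) sprintf("r%dc%d", r, c)))
  df <- data.frame(frame = seq_len(d[1L]) - 1L, pm, check.names = FALSE)
  names(df) <- c("frame", cn)
  utils::write.csv(df, path, row.names = FALSE)
  side <- movie_sidecar_path(path)
  jsonlite::write_json(
    list(dt_ms = stack$dt, pixel_size_mm = stack$pixel_size,
         channel = stack$channel, rows = d[2L], cols = d[3L],
         mask = stack$mask * 1L),
    side, auto_unbox = TRUE, digits = NA)
  invisible(c(csv = path, sidecar = side))
}

#' Read a movie stack from CSV + JSON sidecar
#'
#' @param path CSV path written by [write_movie()].
#' @param sidecar Sidecar path (default: `path` with a `.json` extension).
#' @return A [movie_stack()].
#' @export
read_movie <- function(path, sidecar = NULL) {
  if (is.null(sidecar)) sidecar <- movie_sidecar_path(path)
  if (!file.exists(sidecar)) stopf("sidecar not found: %s", sidecar)
  meta <- jsonlite::fromJSON(sidecar)
  for (f in c("dt_ms", "pixel_size_mm", "rows", "cols")) {
    if (is.null(meta[[f]])) stopf("sidecar is missing `%s`", f)
  }
  df <- utils::read.csv(path, check.names = FALSE)
  npx <- meta$rows * meta$cols
  if (ncol(df) != npx + 1L) {
    stopf("movie shape mismatch: sidecar says %d x %d px (%d columns), CSV has %d",
          meta$rows, meta$cols, npx + 1L, ncol(df))
  }
  pm <- as.matrix(df[, -1L, drop = FALSE])
  frames <- array(pm, dim = c(nrow(pm), meta$rows, meta$cols))
  mask <- NULL
  if (!is.null(meta$mask)) mask <- matrix(as.logical(meta$mask),
                                          meta$rows, meta$cols, byrow = TRUE)
  movie_stack(frames, dt = meta$dt_ms, pixel_size = meta$pixel_size_mm,
              channel = if (is.null(meta$channel)) "voltage" else meta$channel,
              mask = mask)
}

#' Read a photodiode-array recording (wide channel CSV + coordinate table)
#'
#' @param data_csv CSV with one column per channel (rows are frames).
#' @param coords_csv CSV with columns `channel` (matching the data column
#'   names), `row`, `col` (1-based grid positions).
#' @param dt_ms,pixel_size_mm Acquisition metadata (required).
#' @return A [movie_stack()] on the bounding grid, masked `FALSE` wherever
#'   no channel maps.
#' @export
read_photodiode_csv <- function(data_csv, coords_csv, dt_ms, pixel_size_mm) {
  check_number(dt_ms, "dt_ms", 0, strict = TRUE)
  check_number(pixel_size_mm, "pixel_size_mm", 0, strict = TRUE)
  dat <- utils::read.csv(data_csv, check.names = FALSE)
  coo <- utils::read.csv(coords_csv)
  miss <- setdiff(coo$channel, names(dat))
  if (length(miss)) {
    stopf("coordinate table names channels absent from the data: %s",
          paste(utils::head(miss, 5), collapse = ", "))
  }
  nr <- max(coo$row)
  nc <- max(coo$col)
  nt <- nrow(dat)
  frames <- array(0, dim = c(nt, nr, nc))
  mask <- matrix(FALSE, nr, nc)
  for (i in seq_len(nrow(coo))) {
    frames[, coo$row[i], coo$col[i]] <- dat[[as.character(coo$channel[i])]]
    mask[coo$row[i], coo$col[i]] <- TRUE
  }
  movie_stack(frames, dt = dt_ms, pixel_size = pixel_size_mm,
              channel = "voltage", mask = mask)
}

#' Write / read a time-value trace as CSV
#'
#' @param trace data.frame whose first two columns are time and value (e.g.
#'   `time_ms`, `force_mN`).
#' @param path CSV path.
#' @return `write_trace` returns the path invisibly; `read_trace` the
#'   data.frame.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(trace, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) utils::read.csv(path)

#' Write / read a hyperspectral stack (CSV matrix + JSON sidecar)
#'
#' One CSV row per wavelength (column `wavelength_nm`, then pixel columns);
#' the sidecar holds `wavelengths_nm`, `pixel_size_um`, `i_ref`, `rows`,
#' `cols` and the ROI.
#'
#' @param stack A [hyperspectral_stack()].
#' @param path CSV path; sidecar at the `.json` extension.
#' @return Paths (write) / the stack (read).
#' @export
write_hyperspectral <- function(stack, path) {
  stopifnot(inherits(stack, "hyperspectral_stack"))
  d <- dim(stack$images)
  m <- matrix(stack$images, nrow = d[1L])
  df <- data.frame(wavelength_nm = stack$wavelengths, m, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  side <- movie_sidecar_path(path)
  jsonlite::write_json(
    list(wavelengths_nm = stack$wavelengths, pixel_size_um = stack$pixel_size,
         i_ref = stack$i_ref, rows = d[2L], cols = d[3L],
         roi = stack$roi * 1L),
    side, auto_unbox = TRUE, digits = NA)
  invisible(c(csv = path, sidecar = side))
}

#' @rdname write_hyperspectral
#' @export
read_hyperspectral <- function(path, sidecar = NULL) {
  if (is.null(sidecar)) sidecar <- movie_sidecar_path(path)
  meta <- jsonlite::fromJSON(sidecar)
  for (f in c("wavelengths_nm", "pixel_size_um", "rows", "cols")) {
    if (is.null(meta[[f]])) stopf("sidecar is missing `%s`", f)
  }
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  images <- array(m, dim = c(nrow(m), meta$rows, meta$cols))
  roi <- if (is.null(meta$roi)) NULL else
    matrix(as.logical(meta$roi), meta$rows, meta$cols, byrow = TRUE)
  hyperspectral_stack(images, meta$wavelengths_nm, i_ref = meta$i_ref,
                      pixel_size = meta$pixel_size_um, roi = roi)
}

#' Read a run configuration from YAML or JSON
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stopf("config not found: %s", path)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    stopf("config must be .yaml/.yml or .json: %s", path)
  }
}

#' Write an activation/APD-style map as a CSV grid and optional PNG
#'
#' @param m Numeric matrix (NA allowed).
#' @param path CSV path.
#' @param png_path Optional PNG rendering path.
#' @param main Plot title for the PNG.
#' @return Invisibly, the CSV path.
#' @export
write_map_csv <- function(m, path, png_path = NULL, main = "") {
  utils::write.table(m, path, sep = ",", row.names = FALSE, col.names = FALSE)
  if (!is.null(png_path)) {
    grDevices::png(png_path, width = 480, height = 480)
    on.exit(grDevices::dev.off(), add = TRUE)
    graphics::image(t(m)[, nrow(m):1, drop = FALSE], axes = FALSE, main = main,
                    useRaster = TRUE)
  }
  invisible(path)
}
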