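# Beer-Lambert hyperspectral vessel phantom. Vessel footprints are
# rasterized line segments; transmitted intensity at each wavelength follows
# I(lambda) = I0 * 10^-(eps_HbO2 * c1 + eps_Hb * c2), where the
# concentrations are relative (molarity x pathlength, M*cm) so no absolute
# quantification is implied.

#' Packaged hemoglobin extinction coefficients
#'
#' Molar extinction of oxy- and deoxy-hemoglobin at the 11 acquisition
#' wavelengths (500-600 nm, 10 nm steps), loaded from the versioned CSV asset
#' shared by the phantom forward model and [unmix_hemoglobin()].
#'
#' @param wavelengths Optional subset of wavelengths (nm) to return, which
#'   must all be present in the asset.
#' @return data.frame with `wavelength_nm`, `eps_hbo2`, `eps_hb` (cm^-1/M).
#' @export
hb_extinction <- function(wavelengths = NULL) {
  path <- system.file("extdata", "hb_extinction_v1.csv", package = "ehtkit")
  tab <- utils::read.csv(path, comment.char = "#")
  if (!is.null(wavelengths)) {
    idx <- match(wavelengths, tab$wavelength_nm)
    if (anyNA(idx)) {
      stopf("no packaged extinction values at %s nm",
            paste(wavelengths[is.na(idx)], collapse = ", "))
    }
    tab <- tab[idx, , drop = FALSE]
    rownames(tab) <- NULL
  }
  tab
}

#' Construct a hyperspectral image stack
#'
#' @param images 3-D array `[wavelength, row, col]` of intensities (> 0 where
#'   valid).
#' @param wavelengths Strictly increasing wavelengths in nm, one per image.
#' @param i_ref Reference (incident/background) intensity: a scalar, one
#'   value per wavelength, or a `[wavelength, row, col]` array.
#' @param pixel_size Pixel size in um.
#' @param roi Logical matrix marking the patch ROI; defaults to the full
#'   image.
#' @return A `hyperspectral_stack` object.
#' @export
hyperspectral_stack <- function(images, wavelengths, i_ref, pixel_size,
                                roi = NULL) {
  if (!is.array(images) || length(dim(images)) != 3L) {
    stopf("`images` must be a 3-D array [wavelength, row, col]")
  }
  nl <- dim(images)[1L]
  if (length(wavelengths) != nl) {
    stopf("need one image per wavelength (%d images, %d wavelengths)",
          nl, length(wavelengths))
  }
  if (nl >= 2L && any(diff(wavelengths) <= 0)) {
    stopf("wavelengths must be strictly increasing")
  }
  nr <- dim(images)[2L]
  nc <- dim(images)[3L]
  if (is.null(roi)) roi <- matrix(TRUE, nr, nc)
  if (!identical(dim(roi), c(nr, nc))) stopf("`roi` shape must match images")
  check_number(pixel_size, "pixel_size", 0, strict = TRUE)
  structure(
    list(images = images, wavelengths = wavelengths, i_ref = i_ref,
         pixel_size = pixel_size, roi = roi),
    class = "hyperspectral_stack"
  )
}

#' Configuration for the vessel phantom generator
#'
#' @param rows,cols Image dimensions in pixels.
#' @param pixel_size Pixel size in um.
#' @param wavelengths Acquisition wavelengths in nm (strictly increasing,
#'   default 500-600 nm in 10 nm steps, matching the packaged extinction
#'   asset).
#' @param vessels List of segments, each
#'   `list(from = c(row, col), to = c(row, col), radius = <px>,
#'   c_thb = <M*cm>, so2 = <oxygenated fraction>)`. Radii must be > 0.
#'   The default total hemoglobin `c_thb = 1.5e-5` M*cm gives peak
#'   absorbances near 0.8, typical of superficial microvessels.
#' @param background_intensity Incident intensity I0 (arbitrary units).
#' @param noise_sd Gaussian intensity noise SD as a fraction of I0.
#' @param seed RNG seed.
#' @param roi Optional logical ROI matrix (default: whole image).
#' @return A `vessel_phantom_config` list.
#' @export
vessel_phantom_config <- function(rows = 96, cols = 96, pixel_size = 5,
                                  wavelengths = seq(500, 600, by = 10),
                                  vessels = list(), background_intensity = 1000,
                                  noise_sd = 0, seed = 1L, roi = NULL) {
  if (any(diff(wavelengths) <= 0)) stopf("wavelengths must be strictly increasing")
  for (vs in vessels) {
    if (is.null(vs$radius) || vs$radius <= 0) stopf("vessel radii must be > 0")
  }
  check_number(background_intensity, "background_intensity", 0, strict = TRUE)
  check_number(noise_sd, "noise_sd", 0)
  structure(
    list(rows = as.integer(rows), cols = as.integer(cols),
         pixel_size = pixel_size, wavelengths = wavelengths,
         vessels = vessels, background_intensity = background_intensity,
         noise_sd = noise_sd, seed = seed, roi = roi),
    class = "vessel_phantom_config"
  )
}

# default vessel with sensible optics
phantom_vessel <- function(from, to, radius = 3, c_thb = 1.5e-5, so2 = 0.75) {
  list(from = from, to = to, radius = radius, c_thb = c_thb, so2 = so2)
}

# distance from each pixel center to a segment; rasterize at <= radius
segment_footprint <- function(rows, cols, from, to, radius) {
  rr <- matrix(seq_len(rows), rows, cols)
  cc <- matrix(seq_len(cols), rows, cols, byrow = TRUE)
  ax <- from[2L]; ay <- from[1L]; bx <- to[2L]; by <- to[1L]
  dx <- bx - ax; dy <- by - ay
  len2 <- dx * dx + dy * dy
  if (len2 == 0) {
    d <- sqrt((cc - ax)^2 + (rr - ay)^2)
  } else {
    tt <- pmin(pmax(((cc - ax) * dx + (rr - ay) * dy) / len2, 0), 1)
    d <- sqrt((cc - (ax + tt * dx))^2 + (rr - (ay + tt * dy))^2)
  }
  d <= radius
}

#' Generate a Beer-Lambert hyperspectral vessel phantom
#'
#' @param config A [vessel_phantom_config()]. Zero vessels is allowed (blank
#'   phantom, `bvd_truth = 0`).
#' @return List with `stack` (a [hyperspectral_stack()]), `mask_truth`
#'   (logical vessel footprint), `bvd_truth` (vessel px / ROI px),
#'   `c1_truth`/`c2_truth` (per-pixel oxy/deoxy concentration maps, M*cm).
#' @export
gen_hyperspectral_phantom <- function(config) {
  stopifnot(inherits(config, "vessel_phantom_config"))
  nr <- config$rows; nc <- config$cols
  c1 <- matrix(0, nr, nc)
  c2 <- matrix(0, nr, nc)
  foot <- matrix(FALSE, nr, nc)
  for (vs in config$vessels) {
    fp <- segment_footprint(nr, nc, vs$from, vs$to, vs$radius)
    so2 <- if (is.null(vs$so2)) 0.75 else vs$so2
    take <- fp & (vs$c_thb > c1 + c2)
    c1[take] <- so2 * vs$c_thb
    c2[take] <- (1 - so2) * vs$c_thb
    foot <- foot | fp
  }
  eps <- hb_extinction(config$wavelengths)
  i0 <- config$background_intensity
  nl <- length(config$wavelengths)
  images <- array(0, dim = c(nl, nr, nc))
  for (k in seq_len(nl)) {
    a <- eps$eps_hbo2[k] * c1 + eps$eps_hb[k] * c2
    images[k, , ] <- i0 * 10^(-a)
  }
  if (config$noise_sd > 0) {
    images <- images + with_seed(config$seed, array(
      stats::rnorm(length(images), sd = config$noise_sd * i0), dim(images)))
    images[images <= 0] <- i0 * 1e-6  # keep log-transform defined
  }
  roi <- config$roi
  if (is.null(roi)) roi <- matrix(TRUE, nr, nc)
  mask_truth <- foot & roi
  list(
    stack = hyperspectral_stack(images, config$wavelengths, i_ref = i0,
                                pixel_size = config$pixel_size, roi = roi),
    mask_truth = mask_truth,
    bvd_truth = sum(mask_truth) / sum(roi),
    c1_truth = c1, c2_truth = c2
  )
}
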