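# Kinematic action-potential wave simulator. Waves are purely geometric
# (travel time = distance / speed); no ionic model or reaction-diffusion
# integration is attempted. Each pixel plays back one AP template shifted by
# its activation time, which makes every derived quantity (activation map,
# CV, APD80) available in closed form as ground truth.

#' Piecewise-linear action potential template
#'
#' Shape: linear upstroke (0 to `amplitude` over `upstroke` ms), flat plateau
#' (`plateau` ms), linear repolarization ramp back to 0 (`ramp` ms). The
#' closed forms used as ground truth, for activation defined at the 50%
#' upstroke crossing:
#' * activation offset from template onset: `upstroke / 2`
#' * APD80 (activation to 80% repolarization): `upstroke/2 + plateau + 0.8 * ramp`
#'
#' @param upstroke,plateau,ramp Segment durations in ms (>= 0).
#' @param amplitude Peak amplitude, arbitrary units (> 0).
#' @return An `ap_template` object: a list with the parameters, an evaluator
#'   `value(t)` (t in ms relative to template onset), and the analytic
#'   `act50_offset` and `apd80` in ms.
#' @export
ap_template <- function(upstroke = 10, plateau = 300, ramp = 150,
                        amplitude = 1) {
  check_number(upstroke, "upstroke", 0)
  check_number(plateau, "plateau", 0)
  check_number(ramp, "ramp", 0)
  check_number(amplitude, "amplitude", 0, strict = TRUE)
  value <- function(t) {
    y <- numeric(length(t))
    if (upstroke > 0) {
      on_up <- t >= 0 & t < upstroke
      y[on_up] <- amplitude * t[on_up] / upstroke
    }
    on_pl <- t >= upstroke & t < upstroke + plateau
    y[on_pl] <- amplitude
    if (ramp > 0) {
      on_rp <- t >= upstroke + plateau & t < upstroke + plateau + ramp
      y[on_rp] <- amplitude * (1 - (t[on_rp] - upstroke - plateau) / ramp)
    }
    y
  }
  structure(
    list(upstroke = upstroke, plateau = plateau, ramp = ramp,
         amplitude = amplitude, value = value,
         duration = upstroke + plateau + ramp,
         act50_offset = upstroke / 2,
         apd80 = upstroke / 2 + plateau + 0.8 * ramp),
    class = "ap_template"
  )
}

#' Configuration for the wave simulator
#'
#' Defaults model the photodiode-array acquisition (1 mm effective
#' resolution at 1.2 kHz); see [geometry_photodiode()] / [geometry_camera()]
#' for the two acquisition geometries used throughout.
#'
#' @param rows,cols Grid dimensions (>= 2 each).
#' @param pixel_size Pixel size in mm.
#' @param dt Sampling interval in ms.
#' @param duration Recording duration in ms; must be long enough for the last
#'   pixel to activate and fully repolarize.
#' @param source Either `list(type = "plane", angle_deg = <propagation
#'   direction>)` or `list(type = "point", origin = c(row, col))` (1-based
#'   pixel coordinates of the stimulus).
#' @param cv_true True conduction velocity in cm/s (> 0).
#' @param ap An [ap_template()].
#' @param noise_sd Gaussian noise standard deviation, as a fraction of the
#'   template amplitude.
#' @param seed Integer RNG seed (only used when `noise_sd > 0`).
#' @return A `wave_sim_config` list.
#' @export
wave_sim_config <- function(rows = 21, cols = 24, pixel_size = 1,
                            dt = 1000 / 1200, duration = 800,
                            source = list(type = "plane", angle_deg = 0),
                            cv_true = 25, ap = ap_template(),
                            noise_sd = 0, seed = 1L) {
  if (rows < 2L || cols < 2L) stopf("grid must be at least 2 x 2")
  check_number(pixel_size, "pixel_size", 0, strict = TRUE)
  check_number(dt, "dt", 0, strict = TRUE)
  check_number(duration, "duration", 0, strict = TRUE)
  check_number(cv_true, "cv_true", 0, strict = TRUE)
  check_number(noise_sd, "noise_sd", 0)
  if (!source$type %in% c("plane", "point")) {
    stopf("source type must be 'plane' or 'point'")
  }
  if (!inherits(ap, "ap_template")) stopf("`ap` must be an ap_template()")
  structure(
    list(rows = as.integer(rows), cols = as.integer(cols),
         pixel_size = pixel_size, dt = dt, duration = duration,
         source = source, cv_true = cv_true, ap = ap,
         noise_sd = noise_sd, seed = seed),
    class = "wave_sim_config"
  )
}

#' Photodiode-array acquisition geometry (1 mm / 1.2 kHz)
#'
#' 504 recording sites modelled as a 21 x 24 grid (the true array layout is
#' not published; any layout can be supplied through a channel-coordinate
#' table, see [read_photodiode_csv()]).
#' @return Named list with `rows`, `cols`, `pixel_size` (mm), `dt` (ms).
#' @export
geometry_photodiode <- function() {
  list(rows = 21L, cols = 24L, pixel_size = 1, dt = 1000 / 1200)
}

#' EMCCD camera acquisition geometry (80 um / 125 Hz)
#'
#' Down-scaled to a 40 x 40 tile (the full 512 x 512 sensor is unnecessary
#' for desk-scale validation; spatial and temporal resolution are faithful).
#' @return Named list with `rows`, `cols`, `pixel_size` (mm), `dt` (ms).
#' @export
geometry_camera <- function(rows = 40L, cols = 40L) {
  list(rows = rows, cols = cols, pixel_size = 0.08, dt = 8)
}

#' Simulate a propagating action-potential wave movie
#'
#' @param config A [wave_sim_config()].
#' @return List with:
#'   * `stack`: the [movie_stack()] (`channel = "voltage"`)
#'   * `act_truth`: matrix of true template-onset times (ms), i.e.
#'     source-to-pixel travel time
#'   * `act50_truth`: `act_truth + upstroke/2`, what a 50%-upstroke
#'     activation detector measures
#'   * `apd_truth`: analytic APD80 of the template (scalar ms)
#'   * `cv_true`: the configured speed (cm/s)
#'   * `stim`: stimulus pixel `c(row, col)` for point sources, else `NULL`
#' @export
gen_wave_movie <- function(config) {
  stopifnot(inherits(config, "wave_sim_config"))
  v_mm_ms <- config$cv_true / MM_PER_MS_TO_CM_PER_S
  rr <- matrix(seq_len(config$rows) - 1L, config$rows, config$cols)
  cc <- matrix(seq_len(config$cols) - 1L, config$rows, config$cols,
               byrow = TRUE)
  x <- cc * config$pixel_size
  y <- rr * config$pixel_size
  stim <- NULL
  if (config$source$type == "plane") {
    th <- config$source$angle_deg * pi / 180
    proj <- x * cos(th) + y * sin(th)
    dist <- proj - min(proj)
  } else {
    org <- config$source$origin
    stim <- org
    x0 <- (org[2L] - 1L) * config$pixel_size
    y0 <- (org[1L] - 1L) * config$pixel_size
    dist <- sqrt((x - x0)^2 + (y - y0)^2)
  }
  act <- dist / v_mm_ms
  need <- max(act) + config$ap$duration
  if (need > config$duration) {
    last <- which(act == max(act), arr.ind = TRUE)[1L, ]
    stopf(paste0(
      "duration %g ms too short: pixel (row %d, col %d) activates at ",
      "%.1f ms and needs %.1f ms to repolarize"),
      config$duration, last[1L], last[2L], max(act), need)
  }
  t <- seq(0, config$duration, by = config$dt)
  nt <- length(t)
  # [t, pixel] matrix of template playback shifted per pixel
  tm <- outer(t, as.vector(act), `-`)
  sig <- config$ap$value(as.vector(tm))
  dim(sig) <- dim(tm)
  if (config$noise_sd > 0) {
    sig <- sig + with_seed(config$seed, matrix(
      stats::rnorm(length(sig), sd = config$noise_sd * config$ap$amplitude),
      nrow(sig)))
  }
  frames <- array(sig, dim = c(nt, config$rows, config$cols))
  list(
    stack = movie_stack(frames, dt = config$dt,
                        pixel_size = config$pixel_size, channel = "voltage"),
    act_truth = act,
    act50_truth = act + config$ap$act50_offset,
    apd_truth = config$ap$apd80,
    cv_true = config$cv_true,
    stim = stim
  )
}
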