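# Shared fixture builders. The AP template upstroke is geometry-matched
# (the 125 Hz camera cannot represent a 10 ms upstroke); see the methods
# vignette.

ap_for <- function(geometry) {
  if (geometry == "camera") ap_template(25, 300, 150) else ap_template(10, 300, 150)
}

plane_movie <- function(geometry = "photodiode", cv = 25, angle = 30,
                        noise_sd = 0, seed = 1L) {
  g <- if (geometry == "camera") geometry_camera() else geometry_photodiode()
  ap <- ap_for(geometry)
  th <- angle * pi / 180
  proj_mm <- ((g$cols - 1) * abs(cos(th)) + (g$rows - 1) * abs(sin(th))) *
    g$pixel_size
  dur <- proj_mm / (cv / 100) + ap$duration + 40
  gen_wave_movie(wave_sim_config(
    rows = g$rows, cols = g$cols, pixel_size = g$pixel_size, dt = g$dt,
    duration = dur, source = list(type = "plane", angle_deg = angle),
    cv_true = cv, ap = ap, noise_sd = noise_sd, seed = seed))
}

point_movie <- function(geometry = "photodiode", cv = 25, noise_sd = 0,
                        seed = 1L) {
  g <- if (geometry == "camera") geometry_camera() else geometry_photodiode()
  ap <- ap_for(geometry)
  diag_mm <- sqrt((g$rows - 1)^2 + (g$cols - 1)^2) * g$pixel_size
  dur <- diag_mm / (cv / 100) + ap$duration + 40
  gen_wave_movie(wave_sim_config(
    rows = g$rows, cols = g$cols, pixel_size = g$pixel_size, dt = g$dt,
    duration = dur, source = list(type = "point", origin = c(1, 1)),
    cv_true = cv, ap = ap, noise_sd = noise_sd, seed = seed))
}

# measure mean CV with the package's recommended per-geometry settings
measure_cv <- function(sim, geometry, method = "local_plane") {
  s <- cv_analysis_settings(geometry)
  cond <- condition(sim$stack, smooth_ms = s$smooth_ms)
  amap <- activation_map(cond, stim = sim$stim)
  if (method == "radial_fit") {
    conduction_velocity(amap, method = "radial_fit")$mean_cv
  } else {
    conduction_velocity(amap, k = s$k, presmooth = s$presmooth)$mean_cv
  }
}

# two-vessel phantom used across the vascular tests (fixed stated world)
standard_phantom_config <- function(noise_sd = 0, seed = 1L) {
  vessel_phantom_config(
    rows = 96, cols = 96,
    vessels = list(
      list(from = c(10, 1), to = c(86, 96), radius = 3, c_thb = 1.5e-5,
           so2 = 0.75),
      list(from = c(1, 60), to = c(96, 30), radius = 4, c_thb = 1.5e-5,
           so2 = 0.75)),
    noise_sd = noise_sd, seed = seed)
}

# analytic double-exponential twitch, written out independently of the
# generator internals, for oracle crossings via uniroot
biexp_force <- function(t, amplitude, tau_rise, tau_decay, baseline = 0) {
  tpk <- log(tau_decay / tau_rise) * tau_rise * tau_decay /
    (tau_decay - tau_rise)
  pk <- exp(-tpk / tau_decay) - exp(-tpk / tau_rise)
  ifelse(t < 0, baseline,
         baseline + amplitude * (exp(-t / tau_decay) - exp(-t / tau_rise)) / pk)
}

# oracle crossing by root finding on the analytic waveform
biexp_cross <- function(level_frac, amplitude, tau_rise, tau_decay,
                        side = c("up", "down")) {
  side <- match.arg(side)
  tpk <- log(tau_decay / tau_rise) * tau_rise * tau_decay /
    (tau_decay - tau_rise)
  f <- function(t) biexp_force(t, amplitude, tau_rise, tau_decay) -
    level_frac * amplitude
  if (side == "up") {
    stats::uniroot(f, c(0, tpk), tol = 1e-10)$root
  } else {
    stats::uniroot(f, c(tpk, tau_decay * 20), tol = 1e-10)$root
  }
}
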