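# Parametric isometric twitch-train generator. Twitches are double
# exponentials A * (exp(-t/tau_decay) - exp(-t/tau_rise)) rescaled so the
# peak equals the requested amplitude, riding on a passive baseline; a
# triangular override mode provides exact closed-form kinetics for testing.

#' Configuration for the twitch-train generator
#'
#' @param dt Sampling interval in ms.
#' @param n_twitches Number of stimuli.
#' @param stim_frequency Stimulation frequency in Hz.
#' @param amplitude Twitch amplitude (peak minus baseline) in mN.
#' @param tau_rise,tau_decay Double-exponential time constants in ms; must
#'   satisfy `tau_decay > tau_rise > 0`.
#' @param passive_offset Passive baseline force in mN.
#' @param noise_sd Gaussian noise SD in mN.
#' @param seed Integer RNG seed.
#' @param shape `"biexp"` (default) or `"triangle"`; the triangle uses
#'   `tri_rise`/`tri_decay` ms linear ramps (closed-form 10-90% times are
#'   `0.8 * tri_rise` and `0.8 * tri_decay`).
#' @param tri_rise,tri_decay Triangle ramp durations in ms.
#' @param lead_in Quiet baseline before the first stimulus in ms.
#' @param truncate Allow twitches longer than the stimulation period to be
#'   superposed instead of erroring.
#' @return A `twitch_sim_config` list.
#' @export
twitch_sim_config <- function(dt = 1, n_twitches = 5L, stim_frequency = 1,
                              amplitude = 4, tau_rise = 30, tau_decay = 150,
                              passive_offset = 1, noise_sd = 0, seed = 1L,
                              shape = c("biexp", "triangle"),
                              tri_rise = 100, tri_decay = 200,
                              lead_in = 200, truncate = FALSE) {
  shape <- match.arg(shape)
  check_number(dt, "dt", 0, strict = TRUE)
  check_number(amplitude, "amplitude", 0, strict = TRUE)
  check_number(stim_frequency, "stim_frequency", 0, strict = TRUE)
  check_number(noise_sd, "noise_sd", 0)
  if (shape == "biexp") {
    check_number(tau_rise, "tau_rise", 0, strict = TRUE)
    if (tau_decay <= tau_rise) {
      stopf("tau_decay (%g) must exceed tau_rise (%g)", tau_decay, tau_rise)
    }
  } else {
    check_number(tri_rise, "tri_rise", 0, strict = TRUE)
    check_number(tri_decay, "tri_decay", 0, strict = TRUE)
  }
  structure(
    list(dt = dt, n_twitches = as.integer(n_twitches),
         stim_frequency = stim_frequency, amplitude = amplitude,
         tau_rise = tau_rise, tau_decay = tau_decay,
         passive_offset = passive_offset, noise_sd = noise_sd, seed = seed,
         shape = shape, tri_rise = tri_rise, tri_decay = tri_decay,
         lead_in = lead_in, truncate = isTRUE(truncate)),
    class = "twitch_sim_config"
  )
}

# unit-peak single-twitch evaluator (t in ms from stimulus)
twitch_shape_fun <- function(config) {
  if (config$shape == "triangle") {
    tr <- config$tri_rise
    td <- config$tri_decay
    function(t) {
      y <- numeric(length(t))
      up <- t >= 0 & t < tr
      y[up] <- t[up] / tr
      dn <- t >= tr & t < tr + td
      y[dn] <- 1 - (t[dn] - tr) / td
      y
    }
  } else {
    t1 <- config$tau_rise
    t2 <- config$tau_decay
    tpk <- log(t2 / t1) * t1 * t2 / (t2 - t1)
    pk <- exp(-tpk / t2) - exp(-tpk / t1)
    function(t) {
      y <- numeric(length(t))
      pos <- t >= 0
      y[pos] <- (exp(-t[pos] / t2) - exp(-t[pos] / t1)) / pk
      y
    }
  }
}

# support: time for the noiseless unit twitch to fall below `tol`
twitch_support <- function(config, tol = 0.01) {
  if (config$shape == "triangle") return(config$tri_rise + config$tri_decay)
  # after the peak the slow exponential dominates
  config$tau_decay * log(1 / tol) + config$tau_rise
}

#' Generate a stimulated twitch-force train with known kinetics
#'
#' Ground-truth 10-90% rise/decay/total times are measured by a brute-force
#' scan of the noiseless analytic waveform on a 0.01 ms grid (the "dense-grid
#' oracle"), independent of the trace analysis code.
#'
#' @param config A [twitch_sim_config()].
#' @return List with `trace` (data.frame `time_ms`, `force_mN`), `markers`
#'   (stimulus times in ms), and `truth` (list: `amplitude`, `baseline`,
#'   `rise_ms`, `decay_ms`, `total_ms`, `peak_ms`).
#' @export
gen_twitch_train <- function(config) {
  stopifnot(inherits(config, "twitch_sim_config"))
  period <- 1000 / config$stim_frequency
  supp <- twitch_support(config)
  if (supp > period && !config$truncate) {
    stopf(paste0(
      "single-twitch support (%.0f ms) exceeds the stimulation period ",
      "(%.0f ms); pass truncate = TRUE to superpose"), supp, period)
  }
  shape <- twitch_shape_fun(config)
  markers <- config$lead_in + (seq_len(config$n_twitches) - 1L) * period
  total <- config$lead_in + config$n_twitches * period
  t <- seq(0, total, by = config$dt)
  f <- rep(config$passive_offset, length(t))
  for (m in markers) f <- f + config$amplitude * shape(t - m)
  if (config$noise_sd > 0) {
    f <- f + with_seed(config$seed,
                       stats::rnorm(length(f), sd = config$noise_sd))
  }
  # dense-grid oracle on one noiseless twitch
  tg <- seq(0, supp, by = 0.01)
  yg <- config$amplitude * shape(tg)
  a <- config$amplitude
  pk_i <- which.max(yg)
  up10 <- cross_time(tg, yg, 0.1 * a, "up", before = tg[pk_i])
  up90 <- cross_time(tg, yg, 0.9 * a, "up", before = tg[pk_i])
  dn90 <- cross_time(tg, yg, 0.9 * a, "down", after = tg[pk_i])
  dn10 <- cross_time(tg, yg, 0.1 * a, "down", after = tg[pk_i])
  truth <- list(
    amplitude = a,
    baseline = config$passive_offset,
    rise_ms = up90 - up10,
    decay_ms = dn10 - dn90,
    total_ms = dn10 - up10,
    peak_ms = tg[pk_i]
  )
  list(
    trace = data.frame(time_ms = t, force_mN = f),
    markers = markers,
    truth = truth,
    config = config
  )
}
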