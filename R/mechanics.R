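# Isometric contractile mechanics: twitch segmentation and 10-90% kinetics,
# active/passive force-length curves, passive stiffness over the top three
# strain levels, specific force, force-frequency relationship, and force per
# input cardiomyocyte. Forces in mN, times in ms; 1 mN/mm^2 == 1 kPa.

#' Segment a force trace into twitch windows
#'
#' When stimulus markers are supplied the windows are anchored to them
#' (marker minus a baseline window, up to the next marker). Otherwise
#' twitches are located by peak detection with minimum prominence (as a
#' fraction of the global amplitude) and minimum separation (as a fraction
#' of the median inter-peak period), and windows split midway between peaks.
#'
#' @param trace data.frame with `time_ms`, `force_mN`.
#' @param markers Optional stimulus times in ms.
#' @param baseline_ms Pre-stimulus window kept ahead of each marker.
#' @param min_prominence Fraction of the global peak-to-peak amplitude.
#' @param min_separation Fraction of the median inter-peak period.
#' @return List of twitch windows (data.frames with the trace columns), each
#'   with a `stim_ms` attribute (marker time, or `NA` for detected peaks).
#'   Empty (with a warning) when nothing is found.
#' @export
segment_twitches <- function(trace, markers = NULL, baseline_ms = 100,
                             min_prominence = 0.3, min_separation = 0.5) {
  t <- trace$time_ms
  f <- trace$force_mN
  dt <- stats::median(diff(t))
  if (!is.null(markers) && length(markers)) {
    bounds <- c(markers, max(t) + dt)
    out <- lapply(seq_along(markers), function(i) {
      lo <- markers[i] - baseline_ms
      hi <- bounds[i + 1L] - if (i < length(markers)) 1e-9 else 0
      w <- trace[t >= lo & t <= hi, , drop = FALSE]
      attr(w, "stim_ms") <- markers[i]
      w
    })
    return(out)
  }
  amp <- max(f) - min(f)
  if (amp <= 0) {
    warnf("no twitches found in a flat trace")
    return(list())
  }
  pk <- find_peaks(f, prominence = min_prominence * amp)
  if (length(pk) > 1L) {
    period <- stats::median(diff(pk))
    pk <- find_peaks(f, prominence = min_prominence * amp,
                     min_distance = max(1L, floor(min_separation * period)))
  }
  if (!length(pk)) {
    warnf("no twitches found (prominence threshold %.3g mN)",
          min_prominence * amp)
    return(list())
  }
  mids <- if (length(pk) > 1L) (pk[-length(pk)] + pk[-1L]) / 2 else numeric(0)
  lo_i <- c(1, ceiling(mids))
  hi_i <- c(floor(mids), length(t))
  lapply(seq_along(pk), function(i) {
    w <- trace[lo_i[i]:hi_i[i], , drop = FALSE]
    attr(w, "stim_ms") <- NA_real_
    w
  })
}

#' Twitch kinetics and amplitude from a single-twitch window
#'
#' Baseline is the pre-stimulus mean (`baseline_ms` before the marker) when
#' a stimulus time is known, else the mean of the samples at or below the
#' 10th percentile of force. Rise time is the 10% to 90% upward-crossing
#' interval, decay time the downward 90% to 10% interval, and total time
#' runs from 10% activation to 90% relaxation (10% of amplitude remaining).
#' All crossings are linearly interpolated; flat segments at a threshold
#' resolve to the earliest sample.
#'
#' @param window A twitch window from [segment_twitches()], or any
#'   data.frame with `time_ms`, `force_mN` covering a full rise and at least
#'   90% of the relaxation.
#' @param stim_ms Stimulus time; defaults to the window's `stim_ms`
#'   attribute.
#' @param baseline_ms Width of the pre-stimulus baseline window.
#' @return A `twitch_metrics` list: `amplitude_mN`, `baseline_mN`,
#'   `rise_ms`, `decay_ms`, `total_ms`, `peak_ms`, `decay_defined` (`FALSE`,
#'   with `decay_ms = NA`, when relaxation never reaches 10% of amplitude
#'   inside the window).
#' @export
twitch_metrics <- function(window, stim_ms = NULL, baseline_ms = 100) {
  t <- window$time_ms
  f <- window$force_mN
  if (is.null(stim_ms)) stim_ms <- attr(window, "stim_ms")
  if (!is.null(stim_ms) && !is.na(stim_ms)) {
    pre <- f[t >= stim_ms - baseline_ms & t < stim_ms]
    baseline <- if (length(pre)) mean(pre) else f[1L]
  } else {
    baseline <- mean(f[f <= stats::quantile(f, 0.1)])
  }
  pk_i <- which.max(f)
  amplitude <- f[pk_i] - baseline
  if (amplitude <= 0) stopf("window contains no twitch above baseline")
  lev <- function(frac) baseline + frac * amplitude
  up10 <- cross_time(t, f, lev(0.1), "up", "last", before = t[pk_i])
  up90 <- cross_time(t, f, lev(0.9), "up", "last", before = t[pk_i])
  dn90 <- cross_time(t, f, lev(0.9), "down", "first", after = t[pk_i])
  dn10 <- cross_time(t, f, lev(0.1), "down", "first", after = t[pk_i])
  decay_defined <- !is.na(dn10)
  structure(
    list(amplitude_mN = amplitude, baseline_mN = baseline,
         rise_ms = up90 - up10,
         decay_ms = if (decay_defined) dn10 - dn90 else NA_real_,
         total_ms = if (decay_defined) dn10 - up10 else NA_real_,
         peak_ms = t[pk_i], decay_defined = decay_defined),
    class = "twitch_metrics"
  )
}

#' Build an active/passive force-length curve
#'
#' One recording per strain level: the passive tension is the mean force over
#' the non-stimulated baseline segment, and the active force is the mean
#' twitch amplitude above that passive level during stimulation.
#'
#' @param levels List with one element per strain level, each a list with
#'   `strain_pct` (percent of culture length, e.g. 100-120), `trace`
#'   (data.frame `time_ms`, `force_mN`), `baseline_range` (`c(t0, t1)` ms of
#'   the non-stimulated segment) and `markers` (stimulus times in ms).
#'   Levels missing a baseline segment are skipped with a warning.
#' @param csa Cross-sectional area in mm^2 (an input; never estimated).
#' @return A `force_length_curve`: data.frame `strain_pct`, `passive_mN`,
#'   `active_mN`, plus `csa_mm2`.
#' @export
force_length <- function(levels, csa) {
  check_number(csa, "csa", 0, strict = TRUE)
  rows <- lapply(levels, function(lv) {
    t <- lv$trace$time_ms
    br <- lv$baseline_range
    if (is.null(br) || !any(t >= br[1L] & t <= br[2L])) {
      warnf("strain level %g%%: no baseline segment, skipped", lv$strain_pct)
      return(NULL)
    }
    passive <- mean(lv$trace$force_mN[t >= br[1L] & t <= br[2L]])
    wins <- segment_twitches(lv$trace, markers = lv$markers)
    amps <- vapply(wins, function(w) {
      pk <- max(w$force_mN)
      pk - passive
    }, numeric(1))
    active <- if (length(amps)) mean(pmax(amps, 0)) else 0
    data.frame(strain_pct = lv$strain_pct, passive_mN = passive,
               active_mN = active)
  })
  rows <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rows <- rows[order(rows$strain_pct), , drop = FALSE]
  rownames(rows) <- NULL
  structure(list(curve = rows, csa_mm2 = csa), class = "force_length_curve")
}

#' Passive stiffness from the top of the force-length curve
#'
#' Least-squares slope of passive tension (mN) against strain expressed as a
#' fraction of culture length (e.g. 1.12-1.20), over the three highest
#' strain levels at or above 112%, divided by the cross-sectional area.
#' 1 mN/mm^2 is numerically 1 kPa.
#'
#' @param curve A `force_length_curve` (or a data.frame with `strain_pct`
#'   and `passive_mN`, in which case `csa` must be given).
#' @param csa Cross-sectional area in mm^2; defaults to the curve's.
#' @return Stiffness in kPa.
#' @export
stiffness <- function(curve, csa = NULL) {
  if (inherits(curve, "force_length_curve")) {
    if (is.null(csa)) csa <- curve$csa_mm2
    curve <- curve$curve
  }
  check_number(csa, "csa", 0, strict = TRUE)
  qual <- curve[curve$strain_pct >= 112, , drop = FALSE]
  if (nrow(qual) < 3L) {
    stopf("stiffness needs the three highest strain levels >= 112%% (found %d)",
          nrow(qual))
  }
  top <- qual[order(-qual$strain_pct)[1:3], , drop = FALSE]
  strain_frac <- top$strain_pct / 100
  fit <- stats::lm.fit(cbind(1, strain_frac), top$passive_mN)
  unname(fit$coefficients[2L]) / csa
}

#' Specific force
#'
#' @param active Active force in mN.
#' @param csa Cross-sectional area in mm^2 (> 0).
#' @return Specific force in mN/mm^2 (numerically kPa).
#' @export
specific_force <- function(active, csa) {
  check_number(csa, "csa", 0, strict = TRUE)
  active / csa
}

#' Force-frequency relationship
#'
#' Twitch amplitudes at each pacing frequency are normalized to the 1 Hz
#' amplitude (so 1 Hz maps to 100%); the slope is the least-squares slope of
#' normalized force against frequency in %/Hz.
#'
#' @param amplitudes Twitch amplitudes (mN), one per frequency.
#' @param frequencies Pacing frequencies in Hz; must include 1 Hz.
#' @return An `ffr_result`: `frequencies`, `normalized_pct`, `slope_pct_per_hz`.
#' @export
ffr <- function(amplitudes, frequencies = c(1, 1.5, 2)) {
  if (length(amplitudes) != length(frequencies)) {
    stopf("need one amplitude per frequency")
  }
  i1 <- which(abs(frequencies - 1) < 1e-9)
  if (!length(i1)) stopf("the 1 Hz amplitude is required for normalization")
  normalized <- 100 * amplitudes / amplitudes[i1[1L]]
  fit <- stats::lm.fit(cbind(1, frequencies), normalized)
  structure(
    list(frequencies = frequencies, normalized_pct = normalized,
         slope_pct_per_hz = unname(fit$coefficients[2L])),
    class = "ffr_result"
  )
}

#' Contractile force per input cardiomyocyte
#'
#' @param active Active force in mN.
#' @param input_cells Number of cells seeded (> 0).
#' @param cm_fraction Cardiomyocyte fraction of the input in (0, 1].
#' @return Force per input cardiomyocyte in nN/cell
#'   (`active * 1e6 / (input_cells * cm_fraction)`).
#' @export
force_per_input_cm <- function(active, input_cells, cm_fraction = 1) {
  check_number(input_cells, "input_cells", 0, strict = TRUE)
  if (cm_fraction <= 0 || cm_fraction > 1) {
    stopf("`cm_fraction` must be in (0, 1]")
  }
  active * 1e6 / (input_cells * cm_fraction)
}
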