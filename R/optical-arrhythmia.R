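# Post-pacing arrhythmia classification (the 60 s sustained/unsustained
# rule), the burst-pacing protocol enumeration, and graft-host coupling
# assessment from paired event lists.

#' Classify a post-pacing activity episode
#'
#' Ectopic activity is detected as upward threshold crossings after the
#' pacing offset (a short grace window after the offset is excluded). The
#' verdict is `"none"` with no events, `"unsustained"` when the activity
#' self-terminates within 60 s of the offset, and `"sustained"` when it
#' persists 60 s or longer.
#'
#' @param trace data.frame with `time_s` and `value` columns.
#' @param pacing_offset Time (s) at which burst pacing ends; must lie inside
#'   the record.
#' @param threshold Absolute detection threshold; default `NULL` uses
#'   `threshold_frac` of the post-offset maximum.
#' @param threshold_frac Fractional threshold (of the post-offset maximum)
#'   used when `threshold` is `NULL`.
#' @param min_amplitude Post-offset signals whose maximum is below this are
#'   treated as quiescent.
#' @param grace_s Grace window after the offset excluded from detection.
#' @param sustained_s The partition boundary (s), 60 by default.
#' @return An `episode_classification`: `verdict`, `ectopic_duration_s`
#'   (last event time minus offset; 0 when none), `pacing_offset_s`,
#'   `n_events`, `capped` (`TRUE` when the record ends less than
#'   `sustained_s` after the offset, so `"sustained"` could not have been
#'   observed).
#' @export
classify_episode <- function(trace, pacing_offset, threshold = NULL,
                             threshold_frac = 0.5, min_amplitude = 1e-9,
                             grace_s = 0.2, sustained_s = 60) {
  t <- trace$time_s
  v <- trace$value
  if (pacing_offset < min(t) || pacing_offset > max(t)) {
    stopf("pacing_offset (%g s) lies outside the record [%g, %g] s",
          pacing_offset, min(t), max(t))
  }
  sel <- t > pacing_offset + grace_s
  capped <- (max(t) - pacing_offset) < sustained_s
  verdict_of <- function(verdict, dur, n) {
    structure(
      list(verdict = verdict, ectopic_duration_s = dur,
           pacing_offset_s = pacing_offset, n_events = n, capped = capped,
           sustained_s = sustained_s),
      class = "episode_classification")
  }
  if (!any(sel)) return(verdict_of("none", 0, 0L))
  vv <- v[sel]
  tt <- t[sel]
  if (max(vv) < min_amplitude) return(verdict_of("none", 0, 0L))
  thr <- if (is.null(threshold)) threshold_frac * max(vv) else threshold
  up <- which(vv[-1L] >= thr & vv[-length(vv)] < thr)
  if (!length(up)) return(verdict_of("none", 0, 0L))
  last_event <- tt[up[length(up)] + 1L]
  dur <- last_event - pacing_offset
  verdict <- if (dur >= sustained_s) "sustained" else "unsustained"
  verdict_of(verdict, dur, length(up))
}

#' @export
print.episode_classification <- function(x, ...) {
  cat(sprintf("<episode> %s: %d events, activity %0.1f s after offset%s\n",
              x$verdict, x$n_events, x$ectopic_duration_s,
              if (x$capped) " (record shorter than the decision window)" else ""))
  invisible(x)
}

#' The burst-pacing protocol frequencies
#'
#' 2 Hz, then 6-20 Hz in steps of 2 Hz: nine episodes in total.
#'
#' @return Numeric vector of stimulation frequencies in Hz.
#' @export
burst_protocol <- function() {
  c(2, seq(6, 20, by = 2))
}

#' Assess graft-host functional coupling from paired event lists
#'
#' A host activation is "coupled" when a graft event follows it within the
#' latency window. The tissue-level verdict is `"coupled"` when the coupled
#' fraction reaches the threshold, else `"uncoupled"`.
#'
#' @param host_events Host-channel activation times (ms), non-empty.
#' @param graft_events Graft-channel event times (ms); empty means an
#'   electrically silent graft (fraction 0, uncoupled).
#' @param latency_window Window (ms) after each host event in which a graft
#'   event counts as a response.
#' @param coupled_fraction_threshold Minimum coupled fraction for a
#'   `"coupled"` verdict (default 0.8).
#' @return List: `verdict`, `fraction`, `latencies_ms` (first-response
#'   latency per coupled host event), `n_host`.
#' @export
assess_coupling <- function(host_events, graft_events, latency_window = 50,
                            coupled_fraction_threshold = 0.8) {
  if (!length(host_events)) stopf("`host_events` must be non-empty")
  latencies <- rep(NA_real_, length(host_events))
  if (length(graft_events)) {
    graft_events <- sort(graft_events)
    for (i in seq_along(host_events)) {
      h <- host_events[i]
      cand <- graft_events[graft_events >= h &
                             graft_events <= h + latency_window]
      if (length(cand)) latencies[i] <- cand[1L] - h
    }
  }
  frac <- mean(!is.na(latencies))
  list(
    verdict = if (frac >= coupled_fraction_threshold) "coupled" else "uncoupled",
    fraction = frac,
    latencies_ms = latencies[!is.na(latencies)],
    n_host = length(host_events)
  )
}
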