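# Post-burst-pacing episode generator for the 60 s sustained/unsustained
# classification rule: regular paced deflections up to the pacing-offset
# marker, then prescribed ectopic activity (none, < 60 s, or >= 60 s).

#' Generate a synthetic post-pacing activity episode
#'
#' @param kind `"none"`, `"unsustained"` (< 60 s of ectopic activity) or
#'   `"sustained"` (>= 60 s).
#' @param activity_duration Duration of ectopic activity after the pacing
#'   offset, in seconds. Must be consistent with `kind`: 0 for `"none"`,
#'   in (0, 60) for `"unsustained"`, >= 60 for `"sustained"`.
#' @param dt Sample interval in seconds (default 0.01).
#' @param pacing_duration Burst-pacing duration in s (default 1, as in a 1 s
#'   burst protocol).
#' @param pacing_rate,ectopic_rate Deflection rates in Hz.
#' @param tail Extra quiet recording after activity ends, in s; the record
#'   always extends at least 61 s past the offset so the 60 s rule is
#'   decidable.
#' @return List with `trace` (data.frame `time_s`, `value`), `pacing_offset`
#'   (s), `kind`, `activity_duration`.
#' @export
gen_arrhythmia_episode <- function(kind = c("none", "unsustained", "sustained"),
                                   activity_duration = 0, dt = 0.01,
                                   pacing_duration = 1, pacing_rate = 10,
                                   ectopic_rate = 8, tail = 2) {
  kind <- match.arg(kind)
  check_number(activity_duration, "activity_duration", 0)
  ok <- switch(kind,
    none = activity_duration == 0,
    unsustained = activity_duration > 0 && activity_duration < 60,
    sustained = activity_duration >= 60
  )
  if (!ok) {
    stopf("activity_duration = %g s is inconsistent with kind '%s' (none: 0; unsustained: (0, 60); sustained: >= 60)",
          activity_duration, kind)
  }
  lead <- 1
  offset <- lead + pacing_duration
  total <- offset + max(activity_duration + tail, 61)
  t <- seq(0, total, by = dt)
  v <- numeric(length(t))
  put_pulse <- function(v, at) {
    i <- which.min(abs(t - at))
    j <- i:min(i + 1L, length(v))
    v[j] <- 1
    v
  }
  for (p in seq(lead, offset - 1e-9, by = 1 / pacing_rate)) v <- put_pulse(v, p)
  if (activity_duration > 0) {
    # ectopic deflections begin right after the offset and end exactly
    # activity_duration later
    ect <- seq(offset + 1 / ectopic_rate, offset + activity_duration,
               by = 1 / ectopic_rate)
    ect <- c(ect, offset + activity_duration)
    for (p in ect) v <- put_pulse(v, p)
  }
  list(
    trace = data.frame(time_s = t, value = v),
    pacing_offset = offset,
    kind = kind,
    activity_duration = activity_duration
  )
}
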