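# GCaMP flash movie generator: a constant baseline with periodic,
# tissue-wide synchronous transients of prescribed relative amplitude dF/F.

#' Generate a synchronous calcium-flash movie with known dF/F
#'
#' Flashes are triangular-ish (linear rise, exponential-free linear decay)
#' with the peak placed exactly on a frame, so the sampled peak equals
#' `f_base * (1 + dff_true)` and noiseless round-trip recovery is exact.
#'
#' @param dff_true True relative amplitude (F_peak - F_base)/F_base, >= 0.
#' @param rows,cols Image dimensions (default 80 x 80, a ~1.3 mm field at 16 um).
#' @param pixel_size Pixel size in mm (default 0.016, i.e. 16 um intravital
#'   resolution).
#' @param dt Frame interval in ms (default 20, i.e. 50 Hz).
#' @param duration Recording length in ms.
#' @param flash_rate Flash rate in Hz.
#' @param f_base Baseline fluorescence (arbitrary units, > 0).
#' @param rise_frames,decay_frames Flash ramp lengths in frames.
#' @param noise_sd Gaussian noise SD as a fraction of `f_base`.
#' @param seed RNG seed.
#' @return List with `stack` (a calcium [movie_stack()]), `dff_true`,
#'   `flash_times` (ms, peak times), `f_base`.
#' @export
gen_calcium_movie <- function(dff_true, rows = 80, cols = 80,
                              pixel_size = 0.016, dt = 20, duration = 10000,
                              flash_rate = 0.8, f_base = 100,
                              rise_frames = 5L, decay_frames = 10L,
                              noise_sd = 0, seed = 1L) {
  check_number(dff_true, "dff_true", 0)
  check_number(f_base, "f_base", 0, strict = TRUE)
  nt <- floor(duration / dt) + 1L
  t <- (seq_len(nt) - 1L) * dt
  period_fr <- round(1000 / (flash_rate * dt))
  shape <- numeric(nt)
  peak_frames <- integer(0)
  k0 <- rise_frames + 2L
  while (k0 + decay_frames <= nt) {
    up <- seq(k0 - rise_frames, k0)
    shape[up] <- pmax(shape[up], seq(0, 1, length.out = length(up)))
    dn <- seq(k0, k0 + decay_frames)
    shape[dn] <- pmax(shape[dn], seq(1, 0, length.out = length(dn)))
    peak_frames <- c(peak_frames, k0)
    k0 <- k0 + period_fr
  }
  trace <- f_base * (1 + dff_true * shape)
  frames <- array(rep(trace, times = rows * cols), dim = c(nt, rows, cols))
  if (noise_sd > 0) {
    frames <- frames + with_seed(seed, array(
      stats::rnorm(length(frames), sd = noise_sd * f_base), dim(frames)))
  }
  list(
    stack = movie_stack(frames, dt = dt, pixel_size = pixel_size,
                        channel = "calcium"),
    dff_true = dff_true,
    flash_times = (peak_frames - 1L) * dt,
    f_base = f_base
  )
}
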