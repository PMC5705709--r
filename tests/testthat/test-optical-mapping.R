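# Conditioning, activation mapping, isochrones, conduction velocity and
# APD80, including the affine-invariance and time-shift properties.

test_that("conditioning drops dead pixels and normalizes clean ones to [0, 1]", {
  sim <- gen_wave_movie(wave_sim_config(rows = 4, cols = 4, duration = 600))
  st <- sim$stack
  st$frames[, 2, 3] <- 5  # constant-value pixel
  cond <- condition(st)
  expect_false(cond$mask[2, 3])
  expect_equal(sum(!cond$mask), 1L)
  v <- cond$frames[, 1, 1]
  expect_equal(min(v), 0)
  expect_equal(max(v), 1)
})

test_that("conditioning is invariant to per-movie gain and offset", {
  sim <- gen_wave_movie(wave_sim_config(rows = 4, cols = 5, duration = 600,
                                        noise_sd = 0.03, seed = 2L))
  a <- condition(sim$stack)
  st2 <- sim$stack
  st2$frames <- 7.5 * st2$frames + 12
  b <- condition(st2)
  expect_equal(a$frames, b$frames)
  expect_identical(a$mask, b$mask)
})

test_that("an all-flat movie errors naming the SNR threshold", {
  st <- movie_stack(array(3, dim = c(5, 3, 3)), dt = 1, pixel_size = 1)
  expect_error(condition(st), "snr_min = 8")
})

test_that("a clean step activates at the interpolated midpoint", {
  # step from 0 to 1 between frames k = 10 and 11 (0-based): (k + 0.5) dt
  nt <- 40
  frames <- array(0, dim = c(nt, 3, 3))
  frames[12:nt, , ] <- 1  # 1-based frame 12 = 0-based frame 11
  st <- movie_stack(frames, dt = 2, pixel_size = 1)
  cond <- condition(st, snr_min = 0)
  am <- activation_map(cond)
  expect_equal(am$act[2, 2], (10 + 0.5) * 2)
})

test_that("plane-wave activation matches truth within dt/2 everywhere", {
  for (geom in c("photodiode", "camera")) {
    sim <- plane_movie(geom, cv = 25)
    am <- activation_map(condition(sim$stack))
    expect_lt(max(abs(am$act - sim$act50_truth)), sim$stack$dt / 2)
  }
})

test_that("simultaneous activation yields equal times and no resolvable CV", {
  ap <- ap_template(10, 300, 150)
  t <- seq(0, 600, by = 1)
  frames <- array(rep(ap$value(t), times = 9), dim = c(length(t), 3, 3))
  st <- movie_stack(frames, dt = 1, pixel_size = 1)
  am <- activation_map(condition(st, snr_min = 0))
  expect_equal(diff(range(am$act)), 0)
  expect_error(conduction_velocity(am), "no resolvable propagation")
})

test_that("max-derivative activation agrees with half-amplitude on smooth upstrokes", {
  # sigmoid upstroke: unique steepest point at the half-amplitude time
  nr <- 6; nc <- 8; dt <- 1
  act <- matrix(rep(20 + 4 * (seq_len(nc) - 1), each = nr), nr, nc)
  t <- seq(0, 120, by = dt)
  frames <- array(0, dim = c(length(t), nr, nc))
  for (j in seq_len(nc)) {
    for (i in seq_len(nr)) {
      frames[, i, j] <- stats::plogis((t - act[i, j]) / 2)
    }
  }
  cond <- condition(movie_stack(frames, dt = dt, pixel_size = 1), snr_min = 0)
  a <- activation_map(cond, method = "half_amplitude")
  b <- activation_map(cond, method = "max_dvdt")
  expect_lt(max(abs(a$act - act)), dt / 2)
  expect_lt(max(abs(b$act - act)), dt)
})

test_that("isochrone banding counts bands as ceil(range/interval)", {
  act <- matrix(seq(0, 20, length.out = 25), 5, 5)
  am <- activation_map_obj(act, dt = 1, pixel_size = 1)
  iso <- isochrones(am, 5)
  expect_equal(iso$n_bands, 4L)
  expect_equal(sort(unique(as.vector(iso$bands))), 1:4)

  uni <- activation_map_obj(matrix(7, 4, 4), dt = 1, pixel_size = 1)
  expect_equal(isochrones(uni, 5)$n_bands, 1L)
  expect_error(isochrones(am, 0), "interval")
})

test_that("point-source isochrone bands grow with radius", {
  sim <- point_movie("photodiode", cv = 25)
  am <- activation_map(condition(sim$stack), stim = c(1, 1))
  iso <- isochrones(am, 5)
  r <- sqrt(outer((seq_len(nrow(am$act)) - 1)^2,
                  (seq_len(ncol(am$act)) - 1)^2, `+`))
  ord <- order(r)
  expect_true(all(diff(iso$bands[ord]) >= -1e-9 | diff(r[ord]) == 0))
})

test_that("exact closed-form maps give the exact speed under both methods", {
  # plane T = x / 0.25 mm/ms -> 25 cm/s, local plane fit is exact
  nr <- 9; nc <- 11
  act <- matrix(rep((seq_len(nc) - 1) / 0.25, each = nr), nr, nc)
  am <- activation_map_obj(act, dt = 1, pixel_size = 1)
  expect_equal(conduction_velocity(am)$mean_cv, 25)
  # radial T = r / 0.25 from a corner stimulus, radial fit is exact
  r <- sqrt(outer((seq_len(nr) - 1)^2, (seq_len(nc) - 1)^2, `+`))
  am_r <- activation_map_obj(r / 0.25, dt = 1, pixel_size = 1, stim = c(1, 1))
  expect_equal(conduction_velocity(am_r, method = "radial_fit")$mean_cv, 25)
})

test_that("noiseless point-source movies recover CV within 2% by both methods", {
  sim <- point_movie("photodiode", cv = 40)
  am <- activation_map(condition(sim$stack), stim = sim$stim)
  lp <- conduction_velocity(am)
  rf <- conduction_velocity(am, method = "radial_fit")
  expect_lt(abs(lp$mean_cv - 40) / 40, 0.02)
  expect_lt(abs(rf$mean_cv - 40) / 40, 0.02)
  expect_lt(abs(lp$mean_cv - rf$mean_cv) / rf$mean_cv, 0.05)
})

test_that("mean CV equals the mean of the per-pixel speeds used", {
  sim <- plane_movie("photodiode", cv = 20, noise_sd = 0.03, seed = 5L)
  cvr <- conduction_velocity(activation_map(condition(sim$stack, smooth_ms = 4)))
  expect_equal(cvr$mean_cv, mean(cvr$speed[!is.na(cvr$speed)]))
  expect_equal(cvr$n_used, sum(!is.na(cvr$speed)))
})

test_that("APD80 closed form: instant upstroke, 300 ms plateau, 200 ms ramp -> 460", {
  ap <- ap_template(0, 300, 200)
  t <- seq(0, 700, by = 1)
  tr <- ap$value(t - 20)
  frames <- array(rep(tr, times = 9), dim = c(length(t), 3, 3))
  st <- condition(movie_stack(frames, dt = 1, pixel_size = 1), snr_min = 0)
  am <- activation_map(st)
  apd <- apd_map(st, am)
  expect_equal(apd$median_apd, 460, tolerance = 1 / 460)
})

test_that("a square pulse of duration D has APD80 = D within one sample", {
  nt <- 400
  frames <- array(0, dim = c(nt, 2, 2))
  frames[51:250, , ] <- 1  # 200 samples high at dt = 2 -> D = 400 ms
  st <- condition(movie_stack(frames, dt = 2, pixel_size = 1), snr_min = 0)
  am <- activation_map(st)
  apd <- apd_map(st, am)
  expect_lt(abs(apd$median_apd - 400), 2)
})

test_that("synthetic-movie APD80 matches the analytic truth within dt", {
  for (geom in c("photodiode", "camera")) {
    sim <- plane_movie(geom, cv = 25)
    cond <- condition(sim$stack)
    apd <- apd_map(cond, activation_map(cond))
    expect_lt(abs(apd$median_apd - sim$apd_truth), sim$stack$dt)
  }
})

test_that("gain/offset on raw fluorescence changes no derived measurement", {
  sim <- plane_movie("photodiode", cv = 25, noise_sd = 0.03, seed = 3L)
  st2 <- sim$stack
  st2$frames <- 0.4 * st2$frames - 3
  s <- cv_analysis_settings("photodiode")
  c1 <- condition(sim$stack, smooth_ms = s$smooth_ms)
  c2 <- condition(st2, smooth_ms = s$smooth_ms)
  a1 <- activation_map(c1)
  a2 <- activation_map(c2)
  expect_equal(a1$act, a2$act)
  expect_equal(conduction_velocity(a1)$mean_cv,
               conduction_velocity(a2)$mean_cv)
  expect_equal(apd_map(c1, a1)$median_apd, apd_map(c2, a2)$median_apd)
})

test_that("delaying the movie shifts activation and leaves CV/APD unchanged", {
  sim <- plane_movie("photodiode", cv = 25)
  st <- sim$stack
  n_pad <- 24L
  d <- dim(st$frames)
  padded <- array(0, dim = c(d[1] + n_pad, d[2], d[3]))
  padded[(n_pad + 1):(d[1] + n_pad), , ] <- st$frames
  st2 <- movie_stack(padded, dt = st$dt, pixel_size = st$pixel_size)
  c1 <- condition(st)
  c2 <- condition(st2)
  a1 <- activation_map(c1)
  a2 <- activation_map(c2)
  expect_equal(a2$act - a1$act,
               matrix(n_pad * st$dt, d[2], d[3]), tolerance = 1e-8)
  expect_equal(conduction_velocity(a1)$mean_cv,
               conduction_velocity(a2)$mean_cv, tolerance = 1e-8)
  expect_equal(apd_map(c1, a1)$median_apd, apd_map(c2, a2)$median_apd,
               tolerance = 1e-8)
})

test_that("CV round-trips within tolerance across speeds and geometries", {
  # reduced grid here; the full acceptance grid lives in test-acceptance.R
  for (geom in c("photodiode", "camera")) {
    for (cv in c(10, 40)) {
      sim <- plane_movie(geom, cv = cv)
      expect_lt(abs(measure_cv(sim, geom) - cv) / cv, 0.02)
    }
    sim_n <- plane_movie(geom, cv = 25, noise_sd = 0.05, seed = 8L)
    expect_lt(abs(measure_cv(sim_n, geom) - 25) / 25, 0.10)
  }
})
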