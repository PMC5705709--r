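# Ground-truth generators: wave movies, twitch trains, vessel phantoms,
# calcium flashes, arrhythmia episodes.

test_that("plane-wave activation truth follows the d/v closed form", {
  # cv 25 cm/s = 0.25 mm/ms at 1 mm pixels: 4 ms per column along +x
  sim <- gen_wave_movie(wave_sim_config(
    rows = 6, cols = 8, pixel_size = 1, dt = 1, duration = 600,
    source = list(type = "plane", angle_deg = 0), cv_true = 25,
    ap = ap_template(10, 300, 150)))
  expect_equal(unique(round(diff(sim$act_truth[1, ]), 10)), 4.0)
  expect_equal(sim$act_truth[, 1], rep(0, 6))
})

test_that("point-source truth is Euclidean distance over speed", {
  sim <- gen_wave_movie(wave_sim_config(
    rows = 6, cols = 8, pixel_size = 1, dt = 1, duration = 600,
    source = list(type = "point", origin = c(1, 1)), cv_true = 25,
    ap = ap_template(10, 300, 150)))
  # pixel (4, 5) is 5 mm from the corner: 5 / 0.25 = 20 ms
  expect_equal(sim$act_truth[4, 5], 20)
  expect_equal(sim$act_truth[1, 1], 0)
})

test_that("noiseless movies span exactly [0, amplitude] per pixel", {
  sim <- gen_wave_movie(wave_sim_config(
    rows = 4, cols = 4, pixel_size = 1, dt = 0.5, duration = 600,
    cv_true = 25, ap = ap_template(10, 300, 150, amplitude = 1)))
  pm <- matrix(sim$stack$frames, dim(sim$stack$frames)[1])
  expect_equal(unname(apply(pm, 2, max)), rep(1, 16))
  expect_equal(unname(apply(pm, 2, min)), rep(0, 16))
})

test_that("too-short recordings are rejected naming the last pixel", {
  cfg <- wave_sim_config(rows = 6, cols = 8, duration = 100, cv_true = 10)
  expect_error(gen_wave_movie(cfg), "col 8.*activates")
})

test_that("wave generation is bit-stable under a fixed seed", {
  cfg <- wave_sim_config(rows = 5, cols = 5, duration = 600, noise_sd = 0.05,
                         seed = 42L)
  a <- gen_wave_movie(cfg)
  b <- gen_wave_movie(cfg)
  expect_identical(a$stack$frames, b$stack$frames)
})

test_that("triangular twitch truth matches the linear-ramp closed form", {
  sim <- gen_twitch_train(twitch_sim_config(
    shape = "triangle", tri_rise = 100, tri_decay = 200, dt = 1))
  expect_equal(sim$truth$rise_ms, 0.8 * 100, tolerance = 1e-3)
  expect_equal(sim$truth$decay_ms, 0.8 * 200, tolerance = 1e-3)
  expect_equal(sim$truth$total_ms, 0.9 * 100 + 0.9 * 200, tolerance = 1e-3)
})

test_that("biexponential twitch truth matches a root-finding oracle", {
  for (taus in list(c(30, 150), c(20, 100), c(50, 400))) {
    sim <- gen_twitch_train(twitch_sim_config(
      tau_rise = taus[1], tau_decay = taus[2], amplitude = 4,
      stim_frequency = 0.4, n_twitches = 2))  # period > slowest support
    rise <- biexp_cross(0.9, 4, taus[1], taus[2], "up") -
      biexp_cross(0.1, 4, taus[1], taus[2], "up")
    decay <- biexp_cross(0.1, 4, taus[1], taus[2], "down") -
      biexp_cross(0.9, 4, taus[1], taus[2], "down")
    expect_equal(sim$truth$rise_ms, rise, tolerance = 0.02 / rise)
    expect_equal(sim$truth$decay_ms, decay, tolerance = 0.02 / decay)
  }
})

test_that("noiseless twitch trains span [passive, passive + amplitude]", {
  # well-separated twitches, so tails do not stack on the peaks
  sim <- gen_twitch_train(twitch_sim_config(passive_offset = 1, amplitude = 4,
                                            stim_frequency = 0.5,
                                            n_twitches = 2))
  expect_equal(min(sim$trace$force_mN), 1, tolerance = 1e-6)
  expect_equal(max(sim$trace$force_mN), 5, tolerance = 1e-3)
})

test_that("degenerate twitch time constants are rejected", {
  expect_error(twitch_sim_config(tau_rise = 150, tau_decay = 150),
               "tau_decay")
  expect_error(twitch_sim_config(tau_rise = 200, tau_decay = 100),
               "tau_decay")
})

test_that("twitch trains are bit-stable under a fixed seed", {
  cfg <- twitch_sim_config(noise_sd = 0.05, seed = 9L)
  expect_identical(gen_twitch_train(cfg)$trace, gen_twitch_train(cfg)$trace)
})

test_that("blank phantoms have empty truth masks and zero BVD", {
  ph <- gen_hyperspectral_phantom(vessel_phantom_config(rows = 24, cols = 24))
  expect_false(any(ph$mask_truth))
  expect_identical(ph$bvd_truth, 0)
  # all intensities equal the background
  expect_true(all(ph$stack$images == 1000))
})

test_that("single-vessel BVD truth equals the rasterized footprint count", {
  L <- 32
  ph <- gen_hyperspectral_phantom(vessel_phantom_config(
    rows = L, cols = L,
    vessels = list(list(from = c(16, 1), to = c(16, L), radius = 2,
                        c_thb = 1.5e-5, so2 = 0.75))))
  # independent pixel count: horizontal line, |row - 16| <= 2
  expected_px <- sum(abs(matrix(seq_len(L), L, L) - 16) <= 2)
  expect_equal(sum(ph$mask_truth), expected_px)
  expect_equal(ph$bvd_truth, expected_px / L^2)
})

test_that("pure-HbO2 phantom absorbance is proportional to the packaged curve", {
  ph <- gen_hyperspectral_phantom(vessel_phantom_config(
    rows = 16, cols = 16,
    vessels = list(list(from = c(8, 1), to = c(8, 16), radius = 1,
                        c_thb = 1e-5, so2 = 1))))
  px <- which(ph$mask_truth, arr.ind = TRUE)[1, ]
  a <- -log10(ph$stack$images[, px[1], px[2]] / 1000)
  eps <- hb_extinction(ph$stack$wavelengths)
  ratio <- a / eps$eps_hbo2
  expect_lt(diff(range(ratio)) / mean(ratio), 1e-9)
})

test_that("calcium flash movies hit the prescribed peaks", {
  sim <- gen_calcium_movie(1.0, rows = 8, cols = 8, f_base = 100)
  expect_equal(max(sim$stack$frames), 200)
  flat <- gen_calcium_movie(0, rows = 8, cols = 8)
  expect_equal(diff(range(flat$stack$frames)), 0)
  expect_error(gen_calcium_movie(-0.1), "dff_true")
})

test_that("arrhythmia episodes honour the kind/duration contract", {
  ep <- gen_arrhythmia_episode("none")
  post <- ep$trace$value[ep$trace$time_s > ep$pacing_offset + 0.01]
  expect_equal(max(post), 0)

  ep30 <- gen_arrhythmia_episode("unsustained", 30)
  on <- ep30$trace$time_s[ep30$trace$value > 0 &
                            ep30$trace$time_s > ep30$pacing_offset]
  expect_lt(max(on) - ep30$pacing_offset, 30 + 0.1)

  ep70 <- gen_arrhythmia_episode("sustained", 70)
  on70 <- ep70$trace$time_s[ep70$trace$value > 0 &
                              ep70$trace$time_s > ep70$pacing_offset]
  expect_gt(max(on70) - ep70$pacing_offset, 60)

  expect_error(gen_arrhythmia_episode("none", 10), "inconsistent")
  expect_error(gen_arrhythmia_episode("unsustained", 70), "inconsistent")
  expect_error(gen_arrhythmia_episode("sustained", 30), "inconsistent")
})
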