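# Twitch segmentation and kinetics, force-length, stiffness, specific
# force, FFR, and force per input cardiomyocyte.

test_that("a 1 Hz five-twitch train segments into five 1000 ms windows", {
  sim <- gen_twitch_train(twitch_sim_config(n_twitches = 5, stim_frequency = 1))
  wins <- segment_twitches(sim$trace)
  expect_length(wins, 5L)
  starts <- vapply(wins, function(w) w$time_ms[which.max(w$force_mN)],
                   numeric(1))
  expect_equal(unique(round(diff(starts))), 1000)
  # supplied markers anchor windows regardless of detection
  wm <- segment_twitches(sim$trace, markers = sim$markers)
  expect_length(wm, 5L)
  expect_equal(vapply(wm, attr, numeric(1), "stim_ms"), sim$markers)
})

test_that("flat traces yield an empty segmentation with a warning", {
  flat <- data.frame(time_ms = 0:100, force_mN = rep(2, 101))
  expect_warning(w <- segment_twitches(flat), "no twitches")
  expect_length(w, 0L)
})

test_that("triangular twitch metrics follow the linear closed forms", {
  dt <- 0.5
  t <- seq(0, 600, by = dt)
  tr <- 100; td <- 200
  f <- 1 + 4 * pmax(pmin(t / tr, 1 - (t - tr) / td), 0)
  w <- data.frame(time_ms = t, force_mN = f)
  m <- twitch_metrics(w, stim_ms = NULL)
  expect_equal(m$amplitude_mN, 4, tolerance = 1e-6)
  expect_equal(m$rise_ms, 0.8 * tr, tolerance = 1e-6)
  expect_equal(m$decay_ms, 0.8 * td, tolerance = 1e-6)
  expect_equal(m$total_ms, 0.9 * tr + 0.9 * td, tolerance = 1e-6)
})

test_that("generator twitches recover truth kinetics within one sample", {
  for (tr_ in c(20, 50, 100)) {
    for (td_ in c(100, 200, 400)) {
      if (td_ <= tr_) next  # the generator rejects tau_decay <= tau_rise
      cfg <- twitch_sim_config(dt = 1, tau_rise = tr_, tau_decay = td_,
                               stim_frequency = 0.5, n_twitches = 3)
      sim <- gen_twitch_train(cfg)
      # first window: truth metrics describe an isolated twitch, and slow
      # decays leave a (small) tail under the successors
      w <- segment_twitches(sim$trace, markers = sim$markers)[[1]]
      m <- twitch_metrics(w)
      expect_lt(abs(m$rise_ms - sim$truth$rise_ms), cfg$dt)
      expect_lt(abs(m$decay_ms - sim$truth$decay_ms), cfg$dt)
      expect_lt(abs(m$total_ms - sim$truth$total_ms), cfg$dt)
      expect_equal(m$amplitude_mN, sim$truth$amplitude, tolerance = 1e-3)
    }
  }
})

test_that("metrics are baseline-invariant and scale-equivariant", {
  sim <- gen_twitch_train(twitch_sim_config())
  w <- segment_twitches(sim$trace, markers = sim$markers)[[2]]
  m0 <- twitch_metrics(w)
  w_off <- w
  w_off$force_mN <- w_off$force_mN + 3.7
  m1 <- twitch_metrics(w_off)
  expect_equal(m1$rise_ms, m0$rise_ms)
  expect_equal(m1$amplitude_mN, m0$amplitude_mN)
  w_sc <- w
  w_sc$force_mN <- w_sc$force_mN * 2.5
  m2 <- twitch_metrics(w_sc)
  expect_equal(m2$amplitude_mN, 2.5 * m0$amplitude_mN)
  expect_equal(m2$rise_ms, m0$rise_ms, tolerance = 1e-9)
  expect_equal(m2$total_ms, m0$total_ms, tolerance = 1e-9)
})

make_fl_levels <- function(strains = seq(100, 120, 2), active = 4,
                           passive_fun = function(s) 0.1 * (s - 100)) {
  lapply(strains, function(s) {
    sim <- gen_twitch_train(twitch_sim_config(
      amplitude = if (active > 0) active else 1e-12,
      passive_offset = passive_fun(s), n_twitches = 3))
    tr <- sim$trace
    if (active <= 0) tr$force_mN <- rep(passive_fun(s), nrow(tr))
    list(strain_pct = s, trace = tr, baseline_range = c(0, 150),
         markers = sim$markers)
  })
}

test_that("force-length recovers a prescribed passive/active design", {
  fl <- force_length(make_fl_levels(), csa = 0.25)
  expect_equal(nrow(fl$curve), 11L)  # 100-120% in 2% steps
  expect_equal(fl$curve$passive_mN, 0.1 * (fl$curve$strain_pct - 100),
               tolerance = 1e-6)
  expect_equal(fl$curve$active_mN, rep(4, 11), tolerance = 1e-2)
})

test_that("zero stimulation response gives zero active force", {
  fl <- force_length(make_fl_levels(active = 0), csa = 0.25)
  expect_true(all(abs(fl$curve$active_mN) < 1e-6))
})

test_that("stiffness of an affine passive curve is slope/CSA exactly", {
  curve <- data.frame(strain_pct = seq(100, 120, 2),
                      passive_mN = 3 * seq(100, 120, 2) / 100)
  expect_equal(stiffness(curve, csa = 0.3), 10)
  flat <- data.frame(strain_pct = seq(100, 120, 2), passive_mN = rep(1.8, 11))
  expect_equal(stiffness(flat, csa = 0.3), 0)
  short <- data.frame(strain_pct = c(100, 104, 108), passive_mN = 1:3)
  expect_error(stiffness(short, csa = 0.3), ">= 112")
})

test_that("stiffness of an exponential passive curve matches the secant oracle", {
  s <- seq(100, 120, 2)
  p <- 0.05 * exp((s - 100) / 8)
  curve <- data.frame(strain_pct = s, passive_mN = p)
  # least-squares over three equispaced points equals the end-to-end secant
  oracle <- (p[11] - p[9]) / ((s[11] - s[9]) / 100) / 0.3
  expect_equal(stiffness(curve, csa = 0.3), oracle, tolerance = 0.01)
})

test_that("specific force is force over area", {
  expect_equal(specific_force(4, 0.25), 16)
  expect_equal(specific_force(0, 0.25), 0)
  expect_equal(specific_force(4, 0.5), specific_force(4, 0.25) / 2)
  expect_error(specific_force(4, 0), "csa")
})

test_that("FFR normalizes to 1 Hz and regresses the slope", {
  flat <- ffr(c(2, 2, 2), c(1, 1.5, 2))
  expect_equal(flat$normalized_pct, c(100, 100, 100))
  expect_equal(flat$slope_pct_per_hz, 0)

  f <- ffr(c(1, 0.95, 0.83), c(1, 1.5, 2))
  expect_equal(f$normalized_pct, c(100, 95, 83))
  expect_equal(f$slope_pct_per_hz, -17)
  expect_error(ffr(c(1, 2), c(1.5, 2)), "1 Hz")
})

test_that("force per input cardiomyocyte follows the printed arithmetic", {
  expect_equal(force_per_input_cm(5.0, 0.5e6, 1.0), 10.0)
  expect_equal(force_per_input_cm(5.2, 0.5e6, 0.863), 12.05, tolerance = 1e-3)
  expect_equal(force_per_input_cm(5, 1e6, 0.5),
               2 * force_per_input_cm(5, 1e6, 1.0))
  expect_error(force_per_input_cm(5, 0), "input_cells")
})
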