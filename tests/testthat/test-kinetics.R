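# Event linking, dwell-time estimation, normalization, rates, throughput.

test_that("event linking follows the run/gap rules", {
  ev <- link_events(c(10L, 11L, 12L, 40L, 41L), max_gap_frames = 0,
                    exposure = 0.075)
  expect_equal(ev$start_frame, c(10L, 40L))
  expect_equal(ev$end_frame, c(12L, 41L))
  expect_equal(ev$duration, c(3, 2) * 0.075)
  # gap bridging
  ev2 <- link_events(c(10L, 12L), max_gap_frames = 1, exposure = 0.075)
  expect_equal(nrow(ev2), 1)
  expect_equal(ev2$duration, 3 * 0.075)
  expect_equal(nrow(link_events(integer(0), exposure = 0.075)), 0)
})

test_that("linked event counts match the simulated ground truth", {
  cfg <- sim_config(n_frames = 30000L, localization_precision_xy = 1e-6,
                    k_off = 2, rng_seed = 1)
  m <- make_origami_grid(1, 1, 15)
  set.seed(3)
  tr <- simulate_blinking(m, cfg)
  tab <- render_localizations(tr, m, cfg)
  ev <- link_events(tab$locs$frame, max_gap_frames = 0,
                    exposure = cfg$exposure_time)
  n_true <- nrow(tr[[1]]$intervals)
  # detected events = true intervals minus the sub-half-frame ones
  p_miss <- integrate(function(t) pmax(0, 1 - t / 0.075) * 2 * exp(-2 * t),
                      0, 0.075)$value
  expect_equal(nrow(ev) / n_true, 1 - p_miss, tolerance = 0.05)
})

test_that("bright/dark means implement the definitional arithmetic", {
  ev <- link_events(c(10:12, 40:41), max_gap_frames = 0, exposure = 0.075)
  bd <- bright_dark_times(ev, n_frames = 100, exposure = 0.075)
  expect_equal(bd$tau_b, (3 + 2) / 2 * 0.075)
  expect_equal(bd$tau_d_raw, 27 * 0.075)
  expect_true(bd$dark_defined)
  # single event: bright defined, dark flagged
  bd1 <- bright_dark_times(ev[1, ], n_frames = 100, exposure = 0.075)
  expect_equal(bd1$tau_b, 3 * 0.075)
  expect_true(is.na(bd1$tau_d_raw))
  expect_false(bd1$dark_defined)
})

test_that("dark-time normalization follows c/100pM x n_sites", {
  expect_equal(normalize_dark(1.0, 200, 4), 8.0)
  expect_equal(normalize_dark(5.0, 100, 1), 5.0)
  expect_error(normalize_dark(-1, 100, 1), "positive")
  expect_error(normalize_dark(1, 0, 1), "c_pM")
})

test_that("NPC normalization uses expected labeled copies", {
  expect_equal(npc_site_normalization(16, 0.5), 8)
  expect_equal(npc_site_normalization(16, 1.0), 16)
  expect_equal(npc_site_normalization(1, 1.0), 1)
})

test_that("rates invert the dwell times", {
  s <- kinetics_summary(tau_b = 0.5, tau_d_raw = 2, c_pM = 100,
                        n_sites = 12)
  expect_equal(s$k_off, 2)
  expect_equal(s$tau_d_norm, 24)
  r <- estimate_rates(list(tau_b = 0.5, tau_d_norm = 10))
  expect_equal(r$k_off, 2)
  expect_equal(r$k_on, 1e9)
  expect_error(estimate_rates(list(tau_b = 0, tau_d_norm = 1)), "positive")
})

test_that("normalized dark time is invariant to concentration and sites", {
  # same k_on at (c = 50 pM, 12 sites) and (c = 100 pM, 6 sites)
  a <- paintbench:::simulate_and_extract_kinetics(
    seed = 101, k_on = 5e8, k_off = 1, c_pM = 50, rows = 4, cols = 3,
    n_frames = 9000, n_structures = 120)
  b <- paintbench:::simulate_and_extract_kinetics(
    seed = 102, k_on = 5e8, k_off = 1, c_pM = 100, rows = 3, cols = 2,
    n_frames = 9000, n_structures = 120)
  expect_equal(a$tau_d_norm / b$tau_d_norm, 1, tolerance = 0.05)
  # bright time is never rescaled by concentration
  expect_equal(a$tau_b / b$tau_b, 1, tolerance = 0.05)
})

test_that("the sequential-experiment time model reproduces the benchmarks", {
  expect_identical(experiment_time(13, 40, 12, 2), 544)
  expect_identical(experiment_time(1, 40, 0, 2), 40)
  expect_identical(experiment_time(13, 40, 12, 0), 520)
  expect_identical(experiment_time(0, 40, 0, 2), 0)
})

test_that("exponential-tail cross-check agrees with the mean estimator", {
  set.seed(9)
  d <- rexp(20000, rate = 2)
  expect_equal(fit_exponential_tail(d), 2, tolerance = 0.05)
})
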