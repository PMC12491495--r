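# Synthetic-data generator: structures, two-state kinetics, rendering,
# fiducials/drift, exchange rounds.

test_that("origami grids have the designed lattice geometry", {
  g <- make_origami_grid(4, 3, 15)
  expect_equal(nrow(g$sites), 12)
  expect_true(all(g$sites$z == 0))
  expect_equal(colMeans(g$sites[, c("x", "y")]), c(x = 0, y = 0))
  d <- as.matrix(dist(g$sites[, c("x", "y")])); diag(d) <- Inf
  expect_equal(unname(apply(d, 1, min)), rep(15, 12))

  g5 <- make_origami_grid(1, 2, 5)
  expect_equal(nrow(g5$sites), 2)
  expect_equal(sqrt(sum((g5$sites[1, 1:2] - g5$sites[2, 1:2])^2)), 5)

  g1 <- make_origami_grid(1, 1, 15)
  expect_equal(unlist(g1$sites), c(x = 0, y = 0, z = 0))

  expect_error(make_origami_grid(pitch = 0), "pitch")
  expect_error(make_origami_grid(rows = 0), "rows")
})

test_that("NPC model builds two rings of corner pairs", {
  n <- make_npc()
  expect_equal(nrow(n$sites), 32)
  zl <- sort(unique(n$sites$z))
  expect_equal(zl, c(-25, 25))
  # within-pair distances equal pair_spacing by construction
  for (ring in 0:1) {
    for (corner in 0:7) {
      i <- ring * 16 + corner + 1
      j <- ring * 16 + corner + 9
      expect_equal(sqrt(sum((n$sites[i, 1:2] - n$sites[j, 1:2])^2)), 14.3)
    }
  }
  # collapsed pairs
  n0 <- make_npc(pair_spacing = 0)
  xy <- round(as.matrix(n0$sites[n0$sites$z > 0, c("x", "y")]), 9)
  expect_equal(nrow(unique(xy)), 8)
  expect_error(make_npc(copies_per_ring = 15), "even")
})

test_that("filament sites lie on the cylinder surface", {
  set.seed(1)
  f <- make_filament(1000, 15, 500)
  r <- sqrt(f$sites$y^2 + f$sites$z^2)
  expect_equal(r, rep(15, nrow(f$sites)), tolerance = 1e-12)
  f0 <- make_filament(0, 15, 100)
  expect_equal(unique(f0$sites$x), 0)
  # Poisson site count around density * length
  set.seed(2)
  counts <- replicate(40, nrow(make_filament(1000, 15, 1000)$sites))
  expect_gt(mean(counts), 1000 - 4 * sqrt(1000 / 40))
  expect_lt(mean(counts), 1000 + 4 * sqrt(1000 / 40))
  expect_warning(make_filament(1000, 15, 0), "zero")
})

test_that("bright and dark interval means match the two-state rates", {
  cfg <- sim_config(n_frames = 150000L, k_on = 5e8, k_off = 2,
                    imager_concentration = 100, rng_seed = 1)
  m <- make_origami_grid(4, 4, 15)
  set.seed(11)
  tr <- simulate_blinking(m, cfg)
  iv <- do.call(rbind, lapply(tr, function(t) t$intervals))
  bright <- iv[, 2] - iv[, 1]
  expect_gt(length(bright), 8000)
  expect_equal(mean(bright), 1 / 2, tolerance = 0.03)
  dark <- unlist(lapply(tr, function(t) {
    v <- t$intervals
    if (nrow(v) < 2) return(NULL)
    v[-1, 1] - v[-nrow(v), 2]
  }))
  expect_equal(mean(dark), 1 / (5e8 * 100e-12), tolerance = 0.03)

  # doubling the concentration halves the dark time
  cfg2 <- sim_config(n_frames = 150000L, k_on = 5e8, k_off = 2,
                     imager_concentration = 200, rng_seed = 1)
  set.seed(12)
  tr2 <- simulate_blinking(m, cfg2)
  dark2 <- unlist(lapply(tr2, function(t) {
    v <- t$intervals
    if (nrow(v) < 2) return(NULL)
    v[-1, 1] - v[-nrow(v), 2]
  }))
  expect_equal(mean(dark2) / mean(dark), 0.5, tolerance = 0.05)
})

test_that("labeling efficiency zero silences every site", {
  cfg <- sim_config(n_frames = 100L, labeling_efficiency = 0, rng_seed = 1)
  set.seed(1)
  expect_length(simulate_blinking(make_origami_grid(), cfg), 0)
})

test_that("rendering discretizes intervals onto frames", {
  cfg <- sim_config(n_frames = 100L, localization_precision_xy = 1e-9,
                    localization_precision_z = 1e-9, rng_seed = 1)
  m <- make_origami_grid(1, 1, 15)
  dt <- cfg$exposure_time
  tr <- list(list(site_index = 1L,
                  intervals = cbind(t_start = 10 * dt, t_end = 13 * dt)))
  set.seed(1)
  tab <- render_localizations(tr, m, cfg)
  expect_equal(tab$locs$frame, c(10L, 11L, 12L))
  expect_equal(tab$locs$x * cfg$pixel_size, rep(0, 3), tolerance = 1e-6)
  # one localization per site and frame
  expect_false(any(duplicated(tab$locs[, c("frame", "site")])))
})

test_that("rendered localization noise matches the configured precision", {
  cfg <- sim_config(n_frames = 20000L, localization_precision_xy = 2,
                    rng_seed = 1)
  m <- make_origami_grid(1, 1, 15)
  tr <- list(list(site_index = 1L,
                  intervals = cbind(t_start = 0,
                                    t_end = 20000 * cfg$exposure_time)))
  set.seed(5)
  tab <- render_localizations(tr, m, cfg)
  expect_equal(nrow(tab$locs), 20000)
  expect_equal(sd(tab$locs$x) * cfg$pixel_size, 2, tolerance = 0.05)
  expect_equal(sd(tab$locs$y) * cfg$pixel_size, 2, tolerance = 0.05)
})

test_that("fiducials are always-on and drift is returned as injected", {
  cfg <- sim_config(n_frames = 500L, drift_step = 0, rng_seed = 1)
  tab <- random_loc_table(n = 200, n_frames = 500)
  set.seed(3)
  res <- add_fiducials_and_drift(tab, 2L, cfg)
  site <- res$table$locs$site
  fid <- !is.na(site) & site == -1
  expect_equal(sum(fid), 2 * 500)
  expect_equal(res$drift$dx, rep(0, 500))
  # non-fiducial records unchanged under zero drift
  expect_equal(res$table$locs$x[!fid][order(res$table$locs$frame[!fid])],
               tab$locs$x[order(tab$locs$frame)])

  cfg2 <- sim_config(n_frames = 500L, drift_step = 1, rng_seed = 1)
  set.seed(4)
  res2 <- add_fiducials_and_drift(tab, 1L, cfg2)
  expect_equal(nrow(res2$drift), 500)
  expect_gt(sd(res2$drift$dx), 0)
})

test_that("exchange rounds activate only the round species plus crosstalk", {
  cfg <- sim_config(n_frames = 400L, crosstalk_rate = 0,
                    localization_precision_xy = 1.5, fov_width = 64L,
                    fov_height = 64L, rng_seed = 7)
  models <- place_structures(list(
    make_origami_grid(2, 2, 15, species_id = 1L, chirality = "R"),
    make_origami_grid(2, 2, 15, species_id = 2L, chirality = "L")), cfg)
  sim <- simulate_exchange_experiment(models, c(1L, 2L), cfg,
                                      n_fiducials = 0L)
  expect_length(sim$tables, 2)
  for (r in 1:2) {
    sp <- sim$tables[[r]]$locs$species
    expect_true(all(sp == r))
  }
  expect_error(simulate_exchange_experiment(models, 3L, cfg),
               "absent")
})

test_that("crosstalk stays within chirality and matches the configured rate", {
  cfg <- sim_config(n_frames = 4000L, crosstalk_rate = 0.01,
                    k_on = 5e8, imager_concentration = 100,
                    localization_precision_xy = 1.5, fov_width = 96L,
                    fov_height = 96L, rng_seed = 9)
  models <- list()
  for (s in 1:4) {
    chir <- if (s <= 2) "R" else "L"
    for (k in 1:4) {
      models[[length(models) + 1L]] <-
        make_origami_grid(4, 3, 15, species_id = s, chirality = chir)
    }
  }
  models <- place_structures(models, cfg)
  sim <- simulate_exchange_experiment(models, 1:4, cfg, n_fiducials = 0L)
  for (r in 1:4) {
    locs <- sim$tables[[r]]$locs
    chir_r <- sim$manifest$round_chirality[r]
    chir_of <- sim$manifest$species_chirality[as.character(locs$species)]
    # no locs on opposite-chirality structures, ever
    expect_true(all(chir_of == chir_r))
  }
  # off-target fraction ~ crosstalk_rate * n_off / (n_on + ct * n_off)
  locs1 <- sim$tables[[1]]$locs
  off <- mean(locs1$species != 1)
  expected <- 0.01 / (1 + 0.01)  # one same-chirality off-target species
  expect_lt(abs(off - expected),
            4 * sqrt(expected / nrow(locs1)) + 0.002)
})

test_that("identical seeds give bit-identical tables", {
  a <- small_grid_sim(seed = 5, n_structures = 2, n_frames = 300)
  b <- small_grid_sim(seed = 5, n_structures = 2, n_frames = 300)
  expect_identical(a$sim$tables[[1]]$locs, b$sim$tables[[1]]$locs)
  expect_identical(a$sim$manifest$drift, b$sim$manifest$drift)
  c_ <- small_grid_sim(seed = 6, n_structures = 2, n_frames = 300)
  expect_false(identical(a$sim$tables[[1]]$locs, c_$sim$tables[[1]]$locs))
})

test_that("config validation rejects out-of-range parameters", {
  expect_error(sim_config(k_on = 0), "k_on")
  expect_error(sim_config(labeling_efficiency = 1.5), "labeling")
  expect_error(sim_config(n_frames = 0), "n_frames")
  expect_error(sim_config(exposure_time = -1), "exposure")
})
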