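# Binding-site detection: density clustering, frame analysis, picks.

test_that("a 12-site grid is recovered as exactly 12 accurate clusters", {
  g <- make_origami_grid(4, 3, 15)
  sites <- g$sites
  sites$x <- sites$x + 2000; sites$y <- sites$y + 2000
  tab <- site_loc_table(sites, locs_per_site = 50, sigma = 1.5, seed = 1)
  cs <- cluster_locs(tab, radius = 6.5, min_locs = 5)
  cs <- apply_frame_analysis(cs, tab)
  expect_equal(count_sites(cs), 12)
  # each center within 1 nm of a true site
  for (k in seq_len(12)) {
    d <- sqrt((cs$clusters$x - sites$x[k])^2 +
              (cs$clusters$y - sites$y[k])^2)
    expect_lt(min(d), 1)
  }
  # members are disjoint across clusters
  mem <- unlist(cs$members)
  expect_false(any(duplicated(mem)))
  expect_true(all(cs$clusters$n_locs >= 5))
})

test_that("two sites 5 nm apart merge at the 6.5 nm radius", {
  sites <- data.frame(x = c(2000, 2005), y = c(2000, 2000))
  tab <- site_loc_table(sites, locs_per_site = 80, sigma = 1.4, seed = 2)
  cs <- cluster_locs(tab, radius = 6.5, min_locs = 5)
  expect_equal(nrow(cs$clusters), 1)
})

test_that("clusters below the minimum localization count are dropped", {
  tab <- loc_table(data.frame(frame = 0:3, x = rep(10, 4), y = rep(10, 4)),
                   n_frames = 100, width = 64, height = 64,
                   pixel_size = 130)
  cs <- cluster_locs(tab, radius = 6.5, min_locs = 5)
  expect_equal(nrow(cs$clusters), 0)
  expect_equal(count_sites(cs), 0)
  # empty input gives an empty set, not an error
  empty <- loc_table(data.frame(frame = integer(0), x = numeric(0),
                                y = numeric(0)),
                     n_frames = 10, width = 64, height = 64,
                     pixel_size = 130)
  expect_equal(nrow(cluster_locs(empty)$clusters), 0)
})

test_that("clustering is invariant to input order and global translation", {
  sites <- data.frame(x = c(2000, 2015, 2030), y = rep(2000, 3))
  tab <- site_loc_table(sites, locs_per_site = 40, sigma = 1.5, seed = 3)
  cs1 <- cluster_locs(tab)
  set.seed(4)
  perm <- sample(nrow(tab$locs))
  tab2 <- tab; tab2$locs <- tab$locs[perm, ]
  cs2 <- cluster_locs(tab2)
  o1 <- order(cs1$clusters$x); o2 <- order(cs2$clusters$x)
  expect_equal(cs1$clusters$x[o1], cs2$clusters$x[o2])
  expect_equal(cs1$clusters$n_locs[o1], cs2$clusters$n_locs[o2])
  tab3 <- tab; tab3$locs$x <- tab$locs$x + 7.3; tab3$locs$y <- tab$locs$y - 3.1
  cs3 <- cluster_locs(tab3)
  expect_equal(sort(cs3$clusters$x) - 7.3 * 130, sort(cs1$clusters$x),
               tolerance = 1e-9)
})

test_that("frame analysis accepts stationary binding, rejects bursts", {
  n_frames <- 10000
  set.seed(5)
  expect_true(frame_analysis_filter(sample(0:9999, 200), n_frames))
  # all localizations in the first 5% of the movie
  expect_false(frame_analysis_filter(sample(0:499, 200), n_frames))
  # a single long stuck event fails the window test even if centered
  expect_false(frame_analysis_filter(4750:5250, n_frames))
  # 50 short events spread across the movie pass
  ev <- unlist(lapply(round(seq(100, 9800, length.out = 50)),
                      function(s) s:(s + 3)))
  expect_true(frame_analysis_filter(ev, n_frames))
})

test_that("simulated sticking artifact is rejected, true site accepted", {
  # true site: 50 short events; artifact: one 500-frame event only
  set.seed(6)
  starts <- round(seq(50, 9500, length.out = 50))
  true_frames <- unlist(lapply(starts, function(s) s:(s + 2)))
  art_frames <- 3000:3499
  px <- 130
  locs <- rbind(
    data.frame(frame = true_frames,
               x = (2000 + rnorm(length(true_frames), 0, 1.5)) / px,
               y = (2000 + rnorm(length(true_frames), 0, 1.5)) / px),
    data.frame(frame = art_frames,
               x = (2600 + rnorm(length(art_frames), 0, 1.5)) / px,
               y = (2000 + rnorm(length(art_frames), 0, 1.5)) / px))
  tab <- loc_table(locs, n_frames = 10000, width = 64, height = 64,
                   pixel_size = px)
  cs <- apply_frame_analysis(cluster_locs(tab), tab)
  acc <- cs$clusters$accepted[order(cs$clusters$x)]
  expect_equal(acc, c(TRUE, FALSE))
})

test_that("picks partition localizations with nearest-center tie-breaks", {
  s <- small_grid_sim(seed = 7, n_structures = 4, n_frames = 1500,
                      drift_step = 0, n_fiducials = 0)
  tab <- s$sim$tables[[1]]
  ctr <- t(vapply(s$models, paintbench:::structure_center,
                  numeric(2))) / 130
  picks <- pick_regions(tab, data.frame(x = ctr[, 1], y = ctr[, 2]),
                        radius_px = 1)
  expect_length(picks, 4)
  expect_equal(sum(vapply(picks, function(p) nrow(p$locs), integer(1))),
               nrow(tab$locs))
  # far-away center gives an empty pick
  far <- pick_regions(tab, data.frame(x = 1, y = 1), radius_px = 1)
  expect_equal(nrow(far[[1]]$locs), 0)
  # overlapping picks warn and assign each loc once
  expect_warning(
    both <- pick_regions(tab, data.frame(x = c(ctr[1, 1], ctr[1, 1] + 0.5),
                                         y = c(ctr[1, 2], ctr[1, 2])),
                         radius_px = 1),
    "overlapping")
  key <- function(p) paste(p$locs$frame, p$locs$x, p$locs$y)
  expect_length(intersect(key(both[[1]]), key(both[[2]])), 0)
})

test_that("detected site count follows the labeling efficiency", {
  cfg <- sim_config(n_frames = 6000L, labeling_efficiency = 0.5,
                    localization_precision_xy = 1.5, fov_width = 96L,
                    fov_height = 96L, rng_seed = 10)
  models <- place_structures(lapply(1:40, function(i) {
    make_origami_grid(4, 3, 15, species_id = 1L, chirality = "R")
  }), cfg)
  sim <- simulate_exchange_experiment(models, 1L, cfg, n_fiducials = 0L)
  ctr <- t(vapply(models, paintbench:::structure_center, numeric(2))) / 130
  picks <- pick_regions(sim$tables[[1]],
                        data.frame(x = ctr[, 1], y = ctr[, 2]),
                        radius_px = 1)
  n_det <- vapply(picks, function(p) {
    count_sites(apply_frame_analysis(cluster_locs(p), p))
  }, integer(1))
  n_true <- vapply(seq_along(models), function(j) {
    sum(sim$manifest$sites$retained[sim$manifest$sites$structure == j])
  }, integer(1))
  # detection matches ground truth per structure and averages ~6 of 12
  expect_gte(mean(n_det == n_true), 0.95)
  expect_lt(abs(mean(n_det) - 6), 3 * sqrt(12 * 0.25 / 40))
})
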