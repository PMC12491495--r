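# Precision, geometry and crosstalk metrics.

# Table with `n_sites` persistent emitters localized in every frame --
# adjacent-frame NeNA pairs with known ground-truth sigma.
nena_fixture <- function(sigma, n_sites = 40, n_frames = 600, seed = 1,
                         fov = 64, pixel_size = 130) {
  set.seed(seed)
  cx <- runif(n_sites, 5, fov - 5) * pixel_size
  cy <- runif(n_sites, 5, fov - 5) * pixel_size
  n <- n_sites * n_frames
  locs <- data.frame(
    frame = rep(seq_len(n_frames) - 1L, each = n_sites),
    x = (rep(cx, n_frames) + rnorm(n, 0, sigma)) / pixel_size,
    y = (rep(cy, n_frames) + rnorm(n, 0, sigma)) / pixel_size)
  loc_table(locs, n_frames = n_frames, width = fov, height = fov,
            pixel_size = pixel_size)
}

test_that("NeNA is unbiased within 10% across the benchmark precisions", {
  for (sigma in c(1.4, 2.5, 5)) {
    est <- nena_precision(nena_fixture(sigma, seed = round(10 * sigma)))
    expect_gt(est$n_pairs, 10000)
    expect_equal(est$sigma, sigma, tolerance = 0.1)
  }
})

test_that("NeNA needs adjacent-frame pairs", {
  # every localization in a distinct frame: no consecutive-frame pairs
  set.seed(2)
  locs <- data.frame(frame = seq(0, 980, by = 2),
                     x = runif(491, 4, 60), y = runif(491, 4, 60))
  tab <- loc_table(locs, n_frames = 1000, width = 64, height = 64,
                   pixel_size = 130)
  expect_error(nena_precision(tab), "pairs")
})

test_that("site spacing measures nearest-neighbor center distances", {
  g <- make_origami_grid(4, 3, 15)
  sites <- g$sites; sites$x <- sites$x + 2000; sites$y <- sites$y + 2000
  tab <- site_loc_table(sites, locs_per_site = 200, sigma = 1.5, seed = 3)
  cs <- apply_frame_analysis(cluster_locs(tab), tab)
  sp <- site_spacing(cs)
  expect_equal(sp$mean_nn, 15, tolerance = 0.02)
  expect_length(sp$nn_dist, 12)
  # spacing is invariant under rotation/translation of the field
  th <- 0.7
  rot <- tab
  xr <- cos(th) * tab$locs$x - sin(th) * tab$locs$y + 5
  yr <- sin(th) * tab$locs$x + cos(th) * tab$locs$y + 2
  rot$locs$x <- xr; rot$locs$y <- yr
  spr <- site_spacing(apply_frame_analysis(cluster_locs(rot), rot))
  expect_equal(spr$mean_nn, sp$mean_nn, tolerance = 1e-3)
  expect_error(site_spacing(cluster_locs(loc_table(
    data.frame(frame = 0:9, x = rep(10, 10), y = rep(10, 10)),
    n_frames = 10, width = 64, height = 64, pixel_size = 130))),
    "2 accepted")
})

test_that("the two-component fit resolves 5 nm pairs that clustering merges", {
  sites <- data.frame(x = c(2000, 2005), y = c(2000, 2000))
  d <- vapply(1:25, function(s) {
    tab <- site_loc_table(sites, locs_per_site = 150, sigma = 1.4,
                          seed = 100 + s)
    expect_equal(nrow(cluster_locs(tab)$clusters), 1)  # merged at 6.5 nm
    fit_site_pair(tab)$distance
  }, numeric(1))
  expect_equal(mean(d), 5, tolerance = 0.1)
})

test_that("ring separation is recovered by the 1D mixture fit", {
  set.seed(4)
  z <- c(rnorm(3000, -25, 10), rnorm(3000, 25, 10))
  fit <- ring_separation(z)
  expect_false(fit$degenerate)
  expect_equal(fit$delta_z, 50, tolerance = 0.05)
  # identical z values flag as degenerate
  expect_true(ring_separation(rep(3, 200))$degenerate)
  expect_error(ring_separation(rnorm(50)), "100")
})

test_that("filament diameter comes from the cross-section circle fit", {
  # noiseless cylinder: exact recovery
  set.seed(5)
  f <- make_filament(2000, 15, 500)
  fit <- filament_diameter(as.matrix(f$sites))
  # exact up to the data-driven axis estimate
  expect_equal(fit$diameter, 30, tolerance = 0.005)
  expect_equal(abs(fit$axis[1]), 1, tolerance = 1e-6)
  # collinear points are degenerate
  line <- cbind(seq_len(100), 0, 0)
  expect_error(filament_diameter(line), "collinear")
  expect_error(filament_diameter(as.matrix(f$sites)[1:10, ]), ">= 50")
})

test_that("zero-crosstalk chirality-mixed experiments give a diagonal matrix", {
  cfg <- sim_config(n_frames = 800L, crosstalk_rate = 0,
                    localization_precision_xy = 1.5, fov_width = 128L,
                    fov_height = 128L, rng_seed = 21)
  models <- list()
  for (s in 1:12) {
    models[[s]] <- make_origami_grid(4, 3, 15, species_id = s,
                                     chirality = if (s <= 6) "R" else "L")
  }
  models <- place_structures(models, cfg)
  sim <- simulate_exchange_experiment(models, 1:12, cfg, n_fiducials = 0L)
  ct <- crosstalk_matrix(sim$tables, sim$manifest, assign_radius = 10)
  offdiag <- ct$matrix[row(ct$matrix) != col(ct$matrix)]
  expect_identical(unname(offdiag), rep(0, 132))
  expect_true(all(diag(ct$matrix) > 0.99))
  expect_true(all(rowSums(ct$matrix) <= 1 + 1e-12))
})

test_that("nonzero crosstalk appears off-diagonal at the configured rate", {
  cfg <- sim_config(n_frames = 3000L, crosstalk_rate = 0.02,
                    localization_precision_xy = 1.5, fov_width = 96L,
                    fov_height = 96L, rng_seed = 22)
  models <- list()
  for (s in 1:3) {
    for (k in 1:3) {
      models[[length(models) + 1L]] <-
        make_origami_grid(4, 3, 15, species_id = s, chirality = "R")
    }
  }
  models <- place_structures(models, cfg)
  sim <- simulate_exchange_experiment(models, 1:3, cfg, n_fiducials = 0L)
  ct <- crosstalk_matrix(sim$tables, sim$manifest, assign_radius = 10)
  offmass <- 1 - diag(ct$matrix) / rowSums(ct$matrix)
  expected <- 0.02 * 2 / (1 + 0.02 * 2)
  expect_equal(unname(offmass), rep(expected, 3), tolerance = 0.35)
  # diagonal dominance
  for (r in 1:3) {
    expect_gt(ct$matrix[r, r], max(ct$matrix[r, -r]) * 5)
  }
})

test_that("FWHM conversion matches the Gaussian relation", {
  expect_equal(fwhm_resolution(5), 2 * sqrt(2 * log(2)) * 5)
  expect_equal(round(fwhm_resolution(5)), 12)
  expect_equal(fwhm_resolution(0), 0)
  expect_equal(fwhm_resolution(2 * 3.3), 2 * fwhm_resolution(3.3))
})
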