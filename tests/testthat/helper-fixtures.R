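# Shared fixture builders. Everything is generated in code; sizes are kept
# small because each test seeds its own RNG.

# Brute-force sequence oracles, independent of the package code paths.
oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

oracle_max_stem <- function(seq, min_loop = 3) {
  n <- nchar(seq)
  best <- 0
  for (L in seq_len(n %/% 2)) {
    for (i in seq_len(n - L + 1)) {
      for (j in seq_len(n - L + 1)) {
        if (j < i + L + min_loop) next
        a <- substr(seq, i, i + L - 1)
        b <- substr(seq, j, j + L - 1)
        if (oracle_revcomp(a) == b) best <- max(best, L)
      }
    }
  }
  best
}

oracle_lcs <- function(a, b) {
  best <- 0
  for (L in seq_len(min(nchar(a), nchar(b)))) {
    subs_a <- unique(substring(a, 1:(nchar(a) - L + 1), L:nchar(a)))
    subs_b <- unique(substring(b, 1:(nchar(b) - L + 1), L:nchar(b)))
    if (any(subs_a %in% subs_b)) best <- L
  }
  best
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# A localization table with `n` localizations of independent emitters
# scattered uniformly in the FOV (one per frame slot, round-robin).
random_loc_table <- function(n = 1000, n_frames = 50, fov = 64,
                             pixel_size = 130, seed = 1) {
  set.seed(seed)
  locs <- data.frame(frame = rep(seq_len(n_frames) - 1L, length.out = n),
                     x = stats::runif(n, 4, fov - 4),
                     y = stats::runif(n, 4, fov - 4))
  loc_table(locs, n_frames = n_frames, width = fov, height = fov,
            pixel_size = pixel_size, exposure = 0.075)
}

# Localizations from fixed sites: `locs_per_site` draws with isotropic
# Gaussian noise, frames sampled without replacement per site.
site_loc_table <- function(sites_nm, locs_per_site = 50, sigma = 1.5,
                           n_frames = 10000, fov = 64, pixel_size = 130,
                           seed = 1) {
  set.seed(seed)
  parts <- lapply(seq_len(nrow(sites_nm)), function(s) {
    data.frame(
      frame = sample(seq_len(n_frames) - 1L, locs_per_site),
      x = (sites_nm$x[s] + stats::rnorm(locs_per_site, 0, sigma)) /
        pixel_size,
      y = (sites_nm$y[s] + stats::rnorm(locs_per_site, 0, sigma)) /
        pixel_size,
      z = if ("z" %in% names(sites_nm)) sites_nm$z[s] else 0,
      site = s)
  })
  loc_table(do.call(rbind, parts), n_frames = n_frames, width = fov,
            height = fov, pixel_size = pixel_size, exposure = 0.075)
}

# Small single-species exchange simulation used by several tests.
small_grid_sim <- function(seed = 4, n_structures = 9, n_frames = 3000,
                           drift_step = 0.1, n_fiducials = 3,
                           precision = 1.5) {
  cfg <- sim_config(n_frames = n_frames,
                    localization_precision_xy = precision,
                    drift_step = drift_step, fov_width = 64L,
                    fov_height = 64L, rng_seed = seed)
  models <- lapply(seq_len(n_structures), function(i) {
    make_origami_grid(4, 3, 15, species_id = 1L, chirality = "R")
  })
  models <- place_structures(models, cfg)
  sim <- simulate_exchange_experiment(models, 1L, cfg,
                                      n_fiducials = n_fiducials)
  list(sim = sim, models = models, cfg = cfg)
}
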