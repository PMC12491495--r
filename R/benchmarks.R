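# Scenario-level analyses. Each function runs the full synthetic pipeline
# (simulate -> drift-correct -> pick -> cluster -> measure) at desk scale
# and returns the recovered quantities; the acceptance script and the
# acceptance tests call these directly.

# Drop localizations that belong to fiducial markers (standard practice
# before clustering/kinetics: gold beads are masked out of the analysis).
mask_fiducials <- function(table, fiducials, radius_nm = 300) {
  if (is.null(fiducials) || nrow(fiducials) == 0) return(table)
  px <- table$meta$pixel_size
  hit <- nearest_within(table$locs$x * px, table$locs$y * px,
                        fiducials$x * px, fiducials$y * px,
                        radius_nm)$index
  table$locs <- table$locs[is.na(hit), , drop = FALSE]
  table
}

correct_drift <- function(table, min_presence = 0.8, smooth_window = 100L) {
  trace <- track_fiducials(table, min_presence = min_presence,
                           smooth_window = smooth_window)
  undrift(table, trace)
}

#' 12-plex origami scenario: simulate, register and measure site spacing
#'
#' Simulates the 12-species Exchange-PAINT origami experiment (4x3 grids
#' at 15 nm pitch, one species per round, six right- and six left-handed
#' sequences), corrects drift with the fiducial tracks, picks every
#' structure of the round's species at 1 px radius, clusters with the
#' 6.5 nm / 5-localization settings plus frame analysis, and measures the
#' nearest-neighbor distance between detected site centers. Optionally
#' extracts per-species kinetics and the crosstalk matrix from the same
#' data.
#'
#' @param seed Integer seed.
#' @param n_per_species Origami structures per species.
#' @param n_frames Frames per round.
#' @param include_kinetics,include_crosstalk Toggle the extra outputs.
#' @param crosstalk_rate Off-target (same-chirality) binding rate ratio.
#' @return List with `spacing` (mean_nn in nm, all nearest-neighbor
#'   distances, structure count), and optionally `kinetics` (tibble per
#'   species) and `crosstalk` (a `crosstalk_matrix`).
#' @export
analyze_origami12 <- function(seed = 1L, n_per_species = 12L,
                              n_frames = 15000L,
                              include_kinetics = FALSE,
                              include_crosstalk = FALSE,
                              crosstalk_rate = 0) {
  cfg <- sim_config(n_frames = n_frames, localization_precision_xy = 1.5,
                    localization_precision_z = 5, drift_step = 0.1,
                    crosstalk_rate = crosstalk_rate, rng_seed = seed)
  n_species <- 12L
  models <- list()
  for (s in seq_len(n_species)) {
    chir <- if (s <= 6) "R" else "L"
    for (k in seq_len(n_per_species)) {
      models[[length(models) + 1L]] <-
        make_origami_grid(4, 3, 15, species_id = s, chirality = chir)
    }
  }
  models <- place_structures(models, cfg)
  sim <- simulate_exchange_experiment(models, seq_len(n_species), cfg,
                                      n_fiducials = 3L)
  centers <- t(vapply(models, structure_center, numeric(2)))
  species_of <- vapply(models, function(m) m$species_id, integer(1))
  px <- cfg$pixel_size

  nn_all <- list()
  kin_rows <- list()
  corrected <- vector("list", length(sim$tables))
  for (r in seq_along(sim$tables)) {
    tab <- correct_drift(sim$tables[[r]])
    corrected[[r]] <- tab
    tab <- mask_fiducials(tab, sim$manifest$fiducials)
    sp <- sim$manifest$round_species[r]
    ctr <- centers[species_of == sp, , drop = FALSE] / px
    picks <- pick_regions(tab, data.frame(x = ctr[, 1], y = ctr[, 2]),
                          radius_px = 1)
    for (p in picks) {
      if (nrow(p$locs) == 0) next
      cs <- cluster_locs(p, radius = 6.5, min_locs = 5L)
      cs <- apply_frame_analysis(cs, p)
      if (sum(cs$clusters$accepted) >= 2) {
        nn_all[[length(nn_all) + 1L]] <- site_spacing(cs)$nn_dist
      }
    }
    if (include_kinetics) {
      ks <- extract_kinetics(picks, c_pM = cfg$imager_concentration,
                             n_sites = "detected", max_gap_frames = 0L)
      kin_rows[[r]] <- tibble::tibble(
        species = sp,
        chirality = sim$manifest$round_chirality[r],
        tau_b = ks$tau_b, tau_d_raw = ks$tau_d_raw,
        tau_d_norm = ks$tau_d_norm, k_off = ks$k_off, k_on = ks$k_on,
        sites_detected = ks$site_count_mean, n_picks = ks$n_picks)
    }
  }
  nn <- unlist(nn_all, use.names = FALSE)
  out <- list(spacing = list(mean_nn = mean(nn), nn_dist = nn,
                             n_structures = length(models)),
              config = cfg)
  if (include_kinetics) out$kinetics <- do.call(rbind, kin_rows)
  if (include_crosstalk) {
    out$crosstalk <- crosstalk_matrix(corrected, sim$manifest)
  }
  out
}

#' Nuclear-pore scenario: corner-pair distance, ring separation, kinetics
#'
#' Simulates Nup96-style NPCs (two 8-fold rings, corner pairs 14.3 nm,
#' rings 50 nm apart, ~50% labeling), corrects drift, picks each pore at
#' 2 px (260 nm), clusters laterally and pairs each corner's two site
#' clusters by mutual nearest neighbors; the axial ring separation comes
#' from a two-component Gaussian mixture over the pooled z values.
#' Kinetics are normalized with the expected-copy rule
#' (`16 x 50% = 8` effective sites), not with detected clusters.
#'
#' @param seed Integer seed.
#' @param n_npc Number of simulated pores.
#' @param n_frames Frames.
#' @param include_kinetics Also extract bright/dark kinetics.
#' @param pair_range Admissible mutual-nearest-neighbor distance range
#'   (nm) for corner pairing.
#' @return List with `pair_distance` (mean, nm), `pair_dists`,
#'   `ring_separation` (nm), `n_pairs`, and optionally `kinetics`.
#' @export
analyze_npc <- function(seed = 1L, n_npc = 120L, n_frames = 4000L,
                        include_kinetics = FALSE,
                        pair_range = c(5, 25)) {
  cfg <- sim_config(n_frames = n_frames, localization_precision_xy = 2,
                    localization_precision_z = 10,
                    labeling_efficiency = 0.5, drift_step = 0.1,
                    rng_seed = seed)
  models <- lapply(seq_len(n_npc), function(i) {
    make_npc(species_id = 8L, chirality = "L")
  })
  models <- place_structures(models, cfg)
  sim <- simulate_exchange_experiment(models, 8L, cfg, n_fiducials = 3L)
  tab <- correct_drift(sim$tables[[1]])
  tab <- mask_fiducials(tab, sim$manifest$fiducials)
  centers <- t(vapply(models, structure_center, numeric(2))) / cfg$pixel_size
  picks <- pick_regions(tab, data.frame(x = centers[, 1], y = centers[, 2]),
                        radius_px = 2)
  pair_d <- list()
  z_all <- list()
  for (p in picks) {
    if (nrow(p$locs) == 0) next
    z_all[[length(z_all) + 1L]] <- p$locs$z
    cs <- cluster_locs(p, radius = 6.5, min_locs = 5L)
    cs <- apply_frame_analysis(cs, p)
    cl <- cs$clusters[cs$clusters$accepted, , drop = FALSE]
    if (nrow(cl) < 2) next
    dm <- as.matrix(stats::dist(cbind(cl$x, cl$y)))
    diag(dm) <- Inf
    nn <- apply(dm, 1, which.min)
    for (i in seq_len(nrow(cl))) {
      j <- nn[i]
      if (j > i && nn[j] == i &&
          dm[i, j] >= pair_range[1] && dm[i, j] <= pair_range[2]) {
        pair_d[[length(pair_d) + 1L]] <- dm[i, j]
      }
    }
  }
  pair_d <- unlist(pair_d, use.names = FALSE)
  z <- unlist(z_all, use.names = FALSE)
  if (length(z) > 20000) {
    z <- with_seed(derive_seed(seed, 99L), sample(z, 20000))
  }
  ring <- ring_separation(z)
  out <- list(pair_distance = mean(pair_d), pair_dists = pair_d,
              n_pairs = length(pair_d),
              ring_separation = ring$delta_z, ring_fit = ring,
              n_npc = n_npc, config = cfg)
  if (include_kinetics) {
    ks <- extract_kinetics(picks, c_pM = cfg$imager_concentration,
                           n_sites = npc_site_normalization(16, 0.5),
                           max_gap_frames = 0L)
    out$kinetics <- ks
  }
  out
}

#' 5-nm origami scenario: NeNA precision and two-site distance
#'
#' Simulates two-site origami with 5 nm pitch at the high-resolution
#' imaging settings (100 ms exposure, 50 pM imager, 1.4 nm ground-truth
#' precision), corrects drift, and estimates the localization precision
#' with NeNA. Because 5 nm is below the 6.5 nm clustering radius the two
#' sites merge under density clustering, so the site distance uses the
#' two-component mixture fit per pick instead.
#'
#' @param seed Integer seed.
#' @param n_structures Number of two-site origami.
#' @param n_frames Frames.
#' @param fit_pairs Also fit the per-pick two-site distance.
#' @return List with `sigma` (NeNA, nm), `n_pairs`, and optionally
#'   `pair_distance` (mean mixture-fit site distance, nm).
#' @export
analyze_origami5nm <- function(seed = 1L, n_structures = 150L,
                               n_frames = 6000L, fit_pairs = FALSE) {
  cfg <- sim_config(exposure_time = 0.1, n_frames = n_frames,
                    imager_concentration = 50,
                    localization_precision_xy = 1.4,
                    localization_precision_z = 5, drift_step = 0.1,
                    rng_seed = seed)
  models <- lapply(seq_len(n_structures), function(i) {
    make_origami_grid(1, 2, 5, species_id = 12L, chirality = "L")
  })
  models <- place_structures(models, cfg)
  sim <- simulate_exchange_experiment(models, 12L, cfg, n_fiducials = 3L)
  tab <- correct_drift(sim$tables[[1]])
  tab <- mask_fiducials(tab, sim$manifest$fiducials)
  est <- nena_precision(tab, max_dist_nm = 50, min_pairs = 500L)
  out <- list(sigma = est$sigma, n_pairs = est$n_pairs, estimate = est,
              config = cfg)
  if (fit_pairs) {
    centers <- t(vapply(models, structure_center, numeric(2))) /
      cfg$pixel_size
    picks <- pick_regions(tab, data.frame(x = centers[, 1],
                                          y = centers[, 2]),
                          radius_px = 1)
    d <- vapply(picks, function(p) {
      if (nrow(p$locs) < 30) return(NA_real_)
      fit_site_pair(p)$distance
    }, numeric(1))
    out$pair_distance <- mean(d, na.rm = TRUE)
    out$pair_dists <- d[!is.na(d)]
  }
  out
}

#' Tubulin scenario: filament diameter recovery
#'
#' Simulates binding sites on a 15 nm-radius cylinder (the ~30 nm
#' effective diameter of labeled microtubules), renders localizations at
#' 2 nm precision and fits the cross-section circle after projecting out
#' the principal (axis) direction.
#'
#' @param seed Integer seed.
#' @param n_frames Frames.
#' @param filament_length Filament length, nm.
#' @param sites_per_um Site density per micrometre.
#' @return List with `diameter` (nm), `n_points`, and the full fit.
#' @export
analyze_filament <- function(seed = 1L, n_frames = 1500L,
                             filament_length = 2000, sites_per_um = 250) {
  cfg <- sim_config(n_frames = n_frames, localization_precision_xy = 2,
                    localization_precision_z = 2, drift_step = 0,
                    fov_width = 64L, fov_height = 64L, rng_seed = seed)
  model <- with_seed(derive_seed(seed, 7L), {
    make_filament(filament_length, 15, sites_per_um, species_id = 1L,
                  chirality = "L")
  })
  model <- place_structures(list(model), cfg)[[1]]
  sim <- simulate_exchange_experiment(list(model), 1L, cfg,
                                      n_fiducials = 0L)
  tab <- sim$tables[[1]]
  px <- cfg$pixel_size
  pts <- cbind(tab$locs$x * px, tab$locs$y * px, tab$locs$z)
  fit <- filament_diameter(pts)
  list(diameter = fit$diameter, n_points = nrow(pts), fit = fit,
       config = cfg)
}

#' Kinetic parameter recovery across an experimental grid
#'
#' For each (k_on, k_off, c, n_sites) condition, simulates origami
#' structures, runs the full pick/cluster/link/normalize pipeline and
#' compares the recovered rates to the generator truth. Frame counts are
#' sized so each site collects on the order of 15 binding events.
#'
#' @param seed Integer seed.
#' @param combos Data frame with columns `k_on`, `k_off`, `c_pM`, `rows`,
#'   `cols`, `n_frames`; the default grid spans the speed-optimized
#'   regime (k_on 2e8-5e8, bright times 0.5-1 s, 25-100 pM, 8-12 sites).
#' @param n_structures Structures per condition.
#' @return Tibble with the true and recovered rates and their relative
#'   errors per condition.
#' @export
benchmark_kinetics_recovery <- function(seed = 1L, combos = NULL,
                                        n_structures = 150L) {
  if (is.null(combos)) {
    # Frame counts sized for ~15 binding events per site, so that site
    # detection is essentially complete and the detected-site
    # normalization is unbiased.
    combos <- data.frame(
      k_on = c(5e8, 2e8, 5e8, 2e8),
      k_off = c(1, 2, 2, 1),
      c_pM = c(25, 50, 50, 100),
      rows = c(4L, 4L, 4L, 4L),
      cols = c(3L, 3L, 2L, 2L),
      n_frames = c(16200L, 20100L, 8100L, 10200L))
  }
  rows_out <- vector("list", nrow(combos))
  for (k in seq_len(nrow(combos))) {
    cb <- combos[k, ]
    ks <- simulate_and_extract_kinetics(
      seed = derive_seed(seed, 21L, k), k_on = cb$k_on, k_off = cb$k_off,
      c_pM = cb$c_pM, rows = cb$rows, cols = cb$cols,
      n_frames = cb$n_frames, n_structures = n_structures)
    rows_out[[k]] <- tibble::tibble(
      k_on_true = cb$k_on, k_off_true = cb$k_off, c_pM = cb$c_pM,
      n_sites_true = cb$rows * cb$cols,
      tau_b = ks$tau_b, tau_d_norm = ks$tau_d_norm,
      k_off_est = ks$k_off, k_on_est = ks$k_on,
      sites_detected = ks$site_count_mean,
      rel_err_k_off = ks$k_off / cb$k_off - 1,
      rel_err_k_on = ks$k_on / cb$k_on - 1)
  }
  do.call(rbind, rows_out)
}

# One single-species kinetics measurement (grid origami, no drift or
# crosstalk), returning the pipeline's kinetics summary.
simulate_and_extract_kinetics <- function(seed, k_on, k_off, c_pM, rows,
                                          cols, n_frames, n_structures,
                                          n_sites = "detected",
                                          precision_nm = 1.5) {
  cfg <- sim_config(n_frames = n_frames, imager_concentration = c_pM,
                    k_on = k_on, k_off = k_off,
                    localization_precision_xy = precision_nm,
                    localization_precision_z = 5, drift_step = 0,
                    rng_seed = seed)
  models <- lapply(seq_len(n_structures), function(i) {
    make_origami_grid(rows, cols, 15, species_id = 1L, chirality = "R")
  })
  models <- place_structures(models, cfg)
  sim <- simulate_exchange_experiment(models, 1L, cfg, n_fiducials = 0L)
  tab <- sim$tables[[1]]
  centers <- t(vapply(models, structure_center, numeric(2))) /
    cfg$pixel_size
  picks <- pick_regions(tab, data.frame(x = centers[, 1], y = centers[, 2]),
                        radius_px = 1)
  extract_kinetics(picks, c_pM = c_pM, n_sites = n_sites,
                   max_gap_frames = 0L)
}
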