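#' Add fiducial markers and random-walk drift to a localization table
#'
#' Fiducials (gold-nanoparticle stand-ins) emit one localization in every
#' frame at a fixed true position (plus the table's localization noise).
#' A cumulative 2D Gaussian random walk with per-frame step sigma
#' `drift_step` (nm) is then added to *all* localizations. The injected
#' per-frame drift is returned so round-trip tests can compare against the
#' recovered trace.
#'
#' @param table A `loc_table`.
#' @param n_fiducials Number of fiducials (>= 0).
#' @param config A [sim_config()]; supplies `drift_step`, noise and FOV.
#' @param fiducial_positions Optional 2-column matrix/data frame of fixed
#'   fiducial positions in pixels; drawn uniformly inside the FOV margin
#'   when omitted.
#' @param noise_sigma_nm Localization noise sigma for fiducial spots, nm
#'   (defaults to the config's lateral precision).
#' @return A list: `table` (with fiducials and drift applied; fiducial rows
#'   carry `site = -1`), `drift` (tibble `frame`, `dx`, `dy` in pixels) and
#'   `fiducial_positions` (tibble, pixels).
#' @export
add_fiducials_and_drift <- function(table, n_fiducials, config,
                                    fiducial_positions = NULL,
                                    noise_sigma_nm = NULL) {
  validate_loc_table(table)
  validate_sim_config(config)
  if (n_fiducials < 0) stop("n_fiducials must be >= 0", call. = FALSE)
  px <- config$pixel_size
  nf <- config$n_frames
  if (is.null(noise_sigma_nm)) noise_sigma_nm <- config$localization_precision_xy
  locs <- table$locs
  if (n_fiducials > 0) {
    if (is.null(fiducial_positions)) {
      margin <- 8
      fiducial_positions <- cbind(
        x = stats::runif(n_fiducials, margin, config$fov_width - margin),
        y = stats::runif(n_fiducials, margin, config$fov_height - margin))
    }
    fiducial_positions <- as.matrix(fiducial_positions)[, 1:2, drop = FALSE]
    fr <- rep(0:(nf - 1L), times = n_fiducials)
    fid <- rep(seq_len(n_fiducials), each = nf)
    n <- length(fr)
    fid_locs <- tibble::tibble(
      frame = as.integer(fr),
      x = fiducial_positions[fid, 1] + stats::rnorm(n, 0, noise_sigma_nm / px),
      y = fiducial_positions[fid, 2] + stats::rnorm(n, 0, noise_sigma_nm / px),
      z = rep(0, n),
      photons = stats::rpois(n, 10 * config$mean_photons),
      lpx = rep(noise_sigma_nm / px, n),
      lpy = rep(noise_sigma_nm / px, n),
      site = rep(-1L, n)
    )
    if (nrow(locs) == 0) {
      locs <- fid_locs
    } else {
      for (nm in setdiff(names(locs), names(fid_locs))) {
        fid_locs[[nm]] <- rep(NA, nrow(fid_locs))
      }
      for (nm in setdiff(names(fid_locs), names(locs))) {
        locs[[nm]] <- rep(NA, nrow(locs))
      }
      locs <- rbind(locs, fid_locs[, names(locs), drop = FALSE])
    }
  } else {
    fiducial_positions <- matrix(numeric(0), ncol = 2,
                                 dimnames = list(NULL, c("x", "y")))
  }
  drift_nm_x <- cumsum(stats::rnorm(nf, 0, config$drift_step))
  drift_nm_y <- cumsum(stats::rnorm(nf, 0, config$drift_step))
  if (config$drift_step == 0) {
    drift_nm_x <- rep(0, nf); drift_nm_y <- rep(0, nf)
  }
  drift <- tibble::tibble(frame = 0:(nf - 1L),
                          dx = drift_nm_x / px, dy = drift_nm_y / px)
  idx <- locs$frame + 1L
  locs$x <- locs$x + drift$dx[idx]
  locs$y <- locs$y + drift$dy[idx]
  locs <- locs[order(locs$frame), , drop = FALSE]
  out <- table
  out$locs <- locs
  list(table = out,
       drift = drift,
       fiducial_positions = tibble::tibble(x = fiducial_positions[, 1],
                                           y = fiducial_positions[, 2]))
}

#' Simulate a multi-round Exchange-PAINT experiment
#'
#' Produces one localization table per imaging round. In round `s`, sites
#' of species `round_species[s]` bind at the full association rate; sites
#' of other species of the *same chirality* bind at
#' `crosstalk_rate * k_on`; sites of the opposite chirality never bind
#' (mirror-image DNA does not hybridize with natural DNA). Docking-site
#' retention (labeling efficiency) is drawn once per site and held fixed
#' across rounds. Fiducials sit at the same positions in every round;
#' drift is drawn independently per round. All randomness derives from
#' `config$rng_seed` through per-round/per-structure child streams, so
#' identical configs give identical output.
#'
#' @param models List of placed `structure_model`s (see
#'   [place_structures()]).
#' @param round_species Integer vector: the species imaged in each round.
#' @param config A [sim_config()].
#' @param n_fiducials Fiducials per field of view.
#' @return A list with `tables` (list of `loc_table`, one per round) and
#'   `manifest`: ground truth with `sites` (absolute positions, species,
#'   chirality, retention), `fiducials`, per-round `drift` traces and
#'   `round_species`/`round_chirality`.
#' @export
simulate_exchange_experiment <- function(models, round_species, config,
                                         n_fiducials = 3L) {
  validate_sim_config(config)
  species_present <- vapply(models, function(m) m$species_id, integer(1))
  chir <- vapply(models, function(m) m$chirality, character(1))
  if (!all(round_species %in% species_present)) {
    stop("simulate_exchange_experiment: round_species contains species ",
         "absent from `models`: ",
         paste(setdiff(round_species, species_present), collapse = ", "),
         call. = FALSE)
  }
  species_chir <- tapply(chir, species_present, function(x) x[1])
  seed <- config$rng_seed

  # Fixed sample properties: retention per site, fiducial positions.
  retained <- vector("list", length(models))
  for (j in seq_along(models)) {
    retained[[j]] <- with_seed(derive_seed(seed, 1L, j), {
      which(stats::runif(nrow(models[[j]]$sites)) <
              config$labeling_efficiency)
    })
  }
  fid_pos <- with_seed(derive_seed(seed, 2L), {
    margin <- 8
    cbind(x = stats::runif(max(n_fiducials, 1), margin,
                           config$fov_width - margin),
          y = stats::runif(max(n_fiducials, 1), margin,
                           config$fov_height - margin))[seq_len(n_fiducials), ,
                                                        drop = FALSE]
  })

  sites_manifest <- do.call(rbind, lapply(seq_along(models), function(j) {
    m <- models[[j]]
    if (nrow(m$sites) == 0) return(NULL)
    tibble::tibble(structure = m$structure_instance_id,
                   structure_kind = m$structure_kind,
                   species = m$species_id, chirality = m$chirality,
                   site = seq_len(nrow(m$sites)),
                   x = m$sites$x, y = m$sites$y, z = m$sites$z,
                   retained = seq_len(nrow(m$sites)) %in% retained[[j]])
  }))

  tables <- vector("list", length(round_species))
  drifts <- vector("list", length(round_species))
  for (r in seq_along(round_species)) {
    sp <- round_species[r]
    sp_chir <- species_chir[[as.character(sp)]]
    round_tabs <- vector("list", length(models))
    for (j in seq_along(models)) {
      m <- models[[j]]
      scale <- if (m$species_id == sp) 1
               else if (m$chirality == sp_chir) config$crosstalk_rate
               else 0
      if (scale <= 0 || length(retained[[j]]) == 0) next
      sub <- m
      sub$sites <- m$sites[retained[[j]], , drop = FALSE]
      tab <- with_seed(derive_seed(seed, 3L, r, j), {
        traces <- simulate_blinking(sub, config, rate_scale = scale,
                                    apply_labeling = FALSE)
        render_localizations(traces, sub, config)
      })
      if (nrow(tab$locs) > 0) {
        tab$locs$site <- retained[[j]][tab$locs$site]
        tab$locs$structure <- m$structure_instance_id
        tab$locs$species <- m$species_id
        round_tabs[[j]] <- tab$locs
      }
    }
    locs <- do.call(rbind, round_tabs)
    if (is.null(locs)) {
      locs <- tibble::tibble(frame = integer(0), x = numeric(0),
                             y = numeric(0), z = numeric(0),
                             photons = numeric(0), lpx = numeric(0),
                             lpy = numeric(0), site = integer(0),
                             structure = integer(0), species = integer(0))
    }
    tab <- loc_table(locs, n_frames = config$n_frames,
                     width = config$fov_width, height = config$fov_height,
                     pixel_size = config$pixel_size,
                     exposure = config$exposure_time,
                     round_label = sprintf("round%02d_species%d", r, sp))
    withdrift <- with_seed(derive_seed(seed, 4L, r), {
      add_fiducials_and_drift(tab, n_fiducials, config,
                              fiducial_positions = fid_pos)
    })
    tables[[r]] <- withdrift$table
    drifts[[r]] <- withdrift$drift
  }
  list(tables = tables,
       manifest = list(
         sites = sites_manifest,
         fiducials = tibble::tibble(x = fid_pos[, 1], y = fid_pos[, 2]),
         drift = drifts,
         round_species = as.integer(round_species),
         round_chirality = unname(species_chir[as.character(round_species)]),
         species_chirality = species_chir))
}
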