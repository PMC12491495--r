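#' Simulation configuration for Exchange-PAINT synthetic data
#'
#' Bundles the acquisition, kinetic and noise parameters that the
#' synthetic-data generator needs. Defaults reflect the benchmark
#' acquisition settings: 75 ms exposure, 130 nm effective pixel size and a
#' speed-optimized imager regime (association rate of order 5e8 /(M s),
#' bright times of order half a second at dissociation rate 2 /s).
#'
#' @param exposure_time Seconds per camera frame.
#' @param n_frames Number of frames in the acquisition.
#' @param pixel_size Nanometres per camera pixel.
#' @param imager_concentration Imager concentration in pM for the round.
#' @param k_on Association rate constant in 1/(M s).
#' @param k_off Dissociation rate constant in 1/s.
#' @param localization_precision_xy Lateral localization precision sigma, nm.
#' @param localization_precision_z Axial localization precision sigma, nm.
#' @param labeling_efficiency Probability in `[0, 1]` that a designed docking
#'   site is actually present (drawn independently per site).
#' @param crosstalk_rate Relative association rate of an imager to docking
#'   sites of *other* species of the same chirality, in `[0, 1]`. Binding
#'   across chirality classes is always zero, independently of this value.
#' @param drift_step Per-frame random-walk drift step sigma, nm.
#' @param min_on_fraction Minimum fraction of a frame's exposure that a
#'   binding event must cover for that frame to yield a localization.
#' @param fov_width,fov_height Field of view, pixels.
#' @param mean_photons Mean photon count per localization (Poisson).
#' @param rng_seed Integer seed governing all randomness downstream. Child
#'   streams are derived per structure and per round so that results are
#'   reproducible independently of evaluation order.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @export
sim_config <- function(exposure_time = 0.075,
                       n_frames = 15000L,
                       pixel_size = 130,
                       imager_concentration = 100,
                       k_on = 5e8,
                       k_off = 2,
                       localization_precision_xy = 2,
                       localization_precision_z = 10,
                       labeling_efficiency = 1,
                       crosstalk_rate = 0,
                       drift_step = 0,
                       min_on_fraction = 0.5,
                       fov_width = 512L,
                       fov_height = 512L,
                       mean_photons = 2000,
                       rng_seed = 1L) {
  cfg <- list(
    exposure_time = exposure_time,
    n_frames = as.integer(n_frames),
    pixel_size = pixel_size,
    imager_concentration = imager_concentration,
    k_on = k_on,
    k_off = k_off,
    localization_precision_xy = localization_precision_xy,
    localization_precision_z = localization_precision_z,
    labeling_efficiency = labeling_efficiency,
    crosstalk_rate = crosstalk_rate,
    drift_step = drift_step,
    min_on_fraction = min_on_fraction,
    fov_width = as.integer(fov_width),
    fov_height = as.integer(fov_height),
    mean_photons = mean_photons,
    rng_seed = as.integer(rng_seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  for (nm in names(x)) cat(sprintf("  %-26s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  pos <- c("exposure_time", "pixel_size", "imager_concentration",
           "k_on", "k_off", "localization_precision_xy",
           "localization_precision_z")
  for (nm in pos) {
    if (!is.numeric(cfg[[nm]]) || length(cfg[[nm]]) != 1L ||
        !is.finite(cfg[[nm]]) || cfg[[nm]] <= 0) {
      stop("sim_config: `", nm, "` must be a single strictly positive number",
           call. = FALSE)
    }
  }
  for (nm in c("labeling_efficiency", "crosstalk_rate", "min_on_fraction")) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      stop("sim_config: `", nm, "` must lie in `[0, 1]`", call. = FALSE)
    }
  }
  if (cfg$drift_step < 0) stop("sim_config: `drift_step` must be >= 0",
                               call. = FALSE)
  if (cfg$n_frames < 1L) stop("sim_config: `n_frames` must be >= 1",
                              call. = FALSE)
  if (cfg$fov_width < 1L || cfg$fov_height < 1L) {
    stop("sim_config: field of view must be at least 1x1 px", call. = FALSE)
  }
  invisible(cfg)
}

# Imager concentration in molar units.
conc_molar <- function(conc_pM) conc_pM * 1e-12

# Deterministic child seed from a parent seed and integer indices. A small
# multiplicative hash keeps everything below 2^31 so set.seed() accepts it,
# and gives structure/round-level streams that do not depend on evaluation
# order.
derive_seed <- function(seed, ...) {
  ix <- c(...)
  h <- as.numeric(seed) %% 2147483647
  for (k in ix) {
    h <- (h * 69069 + as.numeric(k) + 1) %% 2147483647
  }
  as.integer(h)
}

# Run code under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  code
}
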