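#' NeNA localization-precision estimate
#'
#' Nearest-neighbor-based analysis: repeated localizations of the same
#' emitter in adjacent frames are displaced by sqrt(2) sigma, so the
#' distances between each localization and its nearest neighbor in the
#' *next* frame follow a Rayleigh-type density
#' `p(d) = d / (2 sigma^2) * exp(-d^2 / (4 sigma^2))`, on top of a
#' uniform-area background from unrelated emitters (linear in d). Both
#' components are fitted by maximum likelihood and `sigma` is returned.
#' The estimator needs only the localization list, no raw frames.
#'
#' @param table A `loc_table`.
#' @param max_dist_nm Pair distances beyond this are discarded (also sets
#'   the background support), nm.
#' @param min_pairs Minimum number of adjacent-frame pairs required.
#' @return A `precision_estimate`: list with `sigma` (nm), `method`
#'   (`"NeNA"`), `n_pairs`, `background_weight` and the optimizer result
#'   as `fit`.
#' @export
nena_precision <- function(table, max_dist_nm = 100, min_pairs = 500L) {
  validate_loc_table(table)
  d <- nena_pair_distances(table, max_dist_nm)
  if (length(d) < min_pairs) {
    stop("nena_precision: only ", length(d), " adjacent-frame ",
         "neighbor pairs found (need >= ", min_pairs, "); acquire more ",
         "frames or check that emitters persist across frames",
         call. = FALSE)
  }
  dmax <- max_dist_nm
  nll <- function(par) {
    sigma <- exp(par[1])
    w <- stats::plogis(par[2])
    # Rayleigh component truncated to [0, dmax] (truncation mass is ~1
    # for dmax >> sigma but kept for correctness).
    pray <- 1 - exp(-dmax^2 / (4 * sigma^2))
    f <- w * (d / (2 * sigma^2)) * exp(-d^2 / (4 * sigma^2)) / pray +
      (1 - w) * 2 * d / dmax^2
    -sum(log(pmax(f, 1e-300)))
  }
  init <- c(log(max(stats::median(d) / 1.665, 1e-3)), stats::qlogis(0.8))
  fit <- stats::optim(init, nll, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
  out <- list(sigma = exp(fit$par[1]), method = "NeNA",
              n_pairs = length(d),
              background_weight = 1 - stats::plogis(fit$par[2]),
              fit = fit)
  class(out) <- "precision_estimate"
  out
}

#' @export
print.precision_estimate <- function(x, ...) {
  cat(sprintf("<precision_estimate> sigma = %.3f nm (%s, %d pairs, %.1f%% background)\n",
              x$sigma, x$method, x$n_pairs, 100 * x$background_weight))
  invisible(x)
}

# Distances (nm) from each localization to its nearest neighbor in the
# following frame, capped at max_dist_nm.
nena_pair_distances <- function(table, max_dist_nm) {
  locs <- table$locs
  px <- table$meta$pixel_size
  if (nrow(locs) == 0) return(numeric(0))
  xn <- locs$x * px; yn <- locs$y * px
  by_frame <- split(seq_len(nrow(locs)), locs$frame)
  frames <- as.integer(names(by_frame))
  nxt <- match(frames + 1L, frames)
  out <- vector("list", length(frames))
  for (k in seq_along(frames)) {
    if (is.na(nxt[k])) next
    a <- by_frame[[k]]; b <- by_frame[[nxt[k]]]
    dd <- nearest_within(xn[a], yn[a], xn[b], yn[b], max_dist_nm)$dist
    out[[k]] <- dd[!is.na(dd)]
  }
  unlist(out, use.names = FALSE)
}

#' Nearest-neighbor spacing of detected binding sites
#'
#' @param cs A `cluster_set` with at least two accepted clusters.
#' @return List with `mean_nn` (mean nearest-neighbor center distance,
#'   nm) and `nn_dist` (per-cluster nearest-neighbor distances).
#' @export
site_spacing <- function(cs) {
  stopifnot(inherits(cs, "cluster_set"))
  cl <- cs$clusters[cs$clusters$accepted, , drop = FALSE]
  if (nrow(cl) < 2) {
    stop("site_spacing: need >= 2 accepted clusters", call. = FALSE)
  }
  dm <- as.matrix(stats::dist(cbind(cl$x, cl$y)))
  diag(dm) <- Inf
  nn <- apply(dm, 1, min)
  list(mean_nn = mean(nn), nn_dist = unname(nn))
}

#' Two-site center distance by mixture fit
#'
#' Fallback spacing estimator for site pairs closer than the clustering
#' radius (e.g. the 5-nm origami, merged into one cluster at a 6.5 nm
#' radius): fits a two-component spherical Gaussian mixture to the
#' localizations of one pick and returns the distance between the
#' component means.
#'
#' @param pick_table A `loc_table` restricted to one structure.
#' @return List with `distance` (nm), `centers` (2x2 matrix, nm) and
#'   `degenerate` (TRUE when the components collapse).
#' @export
fit_site_pair <- function(pick_table) {
  validate_loc_table(pick_table)
  px <- pick_table$meta$pixel_size
  xy <- cbind(pick_table$locs$x * px, pick_table$locs$y * px)
  if (nrow(xy) < 10) stop("fit_site_pair: too few localizations",
                          call. = FALSE)
  fit <- mclust::Mclust(xy, G = 2, modelNames = "EII", verbose = FALSE)
  if (is.null(fit)) {
    return(list(distance = NA_real_, centers = NULL, degenerate = TRUE))
  }
  mu <- t(fit$parameters$mean)
  d <- sqrt(sum((mu[1, ] - mu[2, ])^2))
  list(distance = d, centers = mu,
       degenerate = d < 1e-6)
}

#' Axial ring separation from z values
#'
#' Fits a two-component 1D Gaussian mixture (equal variances) to pooled z
#' coordinates and returns the distance between the component means —
#' the estimator used for the ~50 nm separation of the two Nup96 rings.
#'
#' @param z Numeric z values, nm (>= 100 required).
#' @return List with `delta_z` (nm), `mu` (component means), `sigma`
#'   (common sd) and `degenerate`.
#' @export
ring_separation <- function(z) {
  if (length(z) < 100) stop("ring_separation: need >= 100 z values",
                            call. = FALSE)
  if (stats::sd(z) < 1e-9) {
    return(list(delta_z = 0, mu = rep(mean(z), 2), sigma = 0,
                degenerate = TRUE))
  }
  fit <- mclust::Mclust(z, G = 2, modelNames = "E", verbose = FALSE)
  if (is.null(fit)) {
    return(list(delta_z = NA_real_, mu = NULL, sigma = NA_real_,
                degenerate = TRUE))
  }
  mu <- as.vector(fit$parameters$mean)
  delta <- abs(diff(mu))
  sigma <- sqrt(fit$parameters$variance$sigmasq[1])
  list(delta_z = delta, mu = mu, sigma = sigma,
       degenerate = delta < 2 * sigma / sqrt(length(z)))
}

#' Filament diameter from a circle fit to the cross-section
#'
#' The filament axis is taken as the principal direction of the 3D point
#' cloud; points are projected into the normal plane and a circle is
#' fitted by algebraic least squares. The diameter is twice the fitted
#' radius.
#'
#' @param points Matrix/data frame of 3D points (`x`, `y`, `z`) in nm —
#'   e.g. localizations of one filament with x/y scaled to nm.
#' @param min_points Minimum number of points.
#' @return List with `diameter` (nm), `radius`, `center` (in the
#'   projection plane) and `axis` (unit vector).
#' @export
filament_diameter <- function(points, min_points = 50L) {
  pts <- as.matrix(points)[, 1:3, drop = FALSE]
  if (nrow(pts) < min_points) {
    stop("filament_diameter: need >= ", min_points, " points",
         call. = FALSE)
  }
  pc <- stats::prcomp(pts, center = TRUE)
  sdev <- pc$sdev
  if (sdev[2] < 1e-9 || sdev[3] / sdev[2] < 1e-6) {
    stop("filament_diameter: degenerate cross-section (points are ",
         "collinear)", call. = FALSE)
  }
  uv <- pc$x[, 2:3, drop = FALSE]
  # Kasa algebraic circle fit: minimize ||u^2+v^2 - 2au - 2bv - c||.
  A <- cbind(2 * uv[, 1], 2 * uv[, 2], 1)
  rhs <- uv[, 1]^2 + uv[, 2]^2
  sol <- stats::lm.fit(A, rhs)$coefficients
  r <- sqrt(sol[3] + sol[1]^2 + sol[2]^2)
  list(diameter = unname(2 * r), radius = unname(r),
       center = unname(sol[1:2]), axis = unname(pc$rotation[, 1]))
}

#' Crosstalk matrix of an exchange experiment
#'
#' Assigns every localization of each round to the nearest ground-truth
#' binding site within `assign_radius` and tabulates the fraction of the
#' round's localizations landing on each species' structures. Fiducial
#' localizations (anything within `fiducial_radius` of a manifest
#' fiducial) are removed before tabulating. Rows are rounds; with zero
#' crosstalk the matrix is diagonal.
#'
#' Because drift correction only removes the time-varying part of the
#' drift (traces are zero-mean), each round keeps a constant residual
#' offset; when the manifest carries fiducials, every round is first
#' re-anchored by the mean displacement of its fiducial centroids from
#' their true positions -- the per-round channel alignment of a real
#' multiplexed workflow.
#'
#' @param tables List of per-round `loc_table`s (drift-corrected).
#' @param manifest Ground-truth manifest from
#'   [simulate_exchange_experiment()].
#' @param assign_radius Assignment radius, nm; defaults to 5x the typical
#'   per-localization precision in the tables (captures essentially all
#'   on-target mass for 15-nm-scale structures).
#' @param fiducial_radius Exclusion radius around fiducials, nm.
#' @return A `crosstalk_matrix`: list with `matrix` (rounds x species,
#'   dimnames set), `unassigned` (per-round fraction), `species`,
#'   `assign_radius`.
#' @export
crosstalk_matrix <- function(tables, manifest, assign_radius = NULL,
                             fiducial_radius = 300) {
  species <- sort(unique(manifest$sites$species))
  S <- length(species)
  R <- length(tables)
  mat <- matrix(0, R, S,
                dimnames = list(paste0("round", seq_len(R)),
                                paste0("species", species)))
  unassigned <- numeric(R)
  sites <- manifest$sites[manifest$sites$retained, , drop = FALSE]
  for (r in seq_len(R)) {
    tab <- tables[[r]]
    px <- tab$meta$pixel_size
    if (is.null(assign_radius)) {
      lp <- tab$locs$lpx
      assign_radius <- if (length(lp) && all(is.finite(lp))) {
        5 * stats::median(lp) * px
      } else 10
    }
    xn <- tab$locs$x * px; yn <- tab$locs$y * px
    if (nrow(manifest$fiducials) > 0) {
      near_fid <- nearest_within(xn, yn,
                                 manifest$fiducials$x * px,
                                 manifest$fiducials$y * px,
                                 fiducial_radius)$index
      # Re-anchor the round: fiducial centroids vs true positions give
      # the round's constant residual offset.
      have <- !is.na(near_fid)
      if (any(have)) {
        offx <- mean(xn[have] - manifest$fiducials$x[near_fid[have]] * px)
        offy <- mean(yn[have] - manifest$fiducials$y[near_fid[have]] * px)
        xn <- xn - offx; yn <- yn - offy
      }
      keep <- is.na(near_fid)
      xn <- xn[keep]; yn <- yn[keep]
    }
    n <- length(xn)
    if (n == 0) next
    hit <- nearest_within(xn, yn, sites$x, sites$y, assign_radius)$index
    assigned <- !is.na(hit)
    sp_hit <- sites$species[hit[assigned]]
    frac <- tabulate(match(sp_hit, species), nbins = S) / n
    mat[r, ] <- frac
    unassigned[r] <- 1 - sum(frac)
  }
  out <- list(matrix = mat, unassigned = unassigned, species = species,
              assign_radius = assign_radius)
  class(out) <- "crosstalk_matrix"
  out
}

#' @export
print.crosstalk_matrix <- function(x, ...) {
  cat("<crosstalk_matrix> rounds x species fractions\n")
  print(round(x$matrix, 4))
  invisible(x)
}

#' Gaussian FWHM resolution from localization precision
#'
#' `FWHM = 2 * sqrt(2 * ln 2) * sigma ~= 2.3548 sigma`; 5 nm precision
#' gives ~11.8 nm, i.e. the often-quoted ~12 nm spatial resolution.
#'
#' @param sigma Localization precision, nm (>= 0).
#' @return FWHM in nm.
#' @export
fwhm_resolution <- function(sigma) {
  stopifnot(all(sigma >= 0))
  2 * sqrt(2 * log(2)) * sigma
}
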