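#' Ground-truth structure model
#'
#' A structure model carries the true docking-site coordinates (nm) of one
#' nanostructure together with its species label (which imager sequence
#' binds it) and chirality class ("R" for natural right-handed DNA, "L" for
#' mirror-image left-handed DNA).
#'
#' @param sites Data frame with numeric columns `x`, `y`, `z` in nm.
#' @param species_id Integer species label (one per docking sequence).
#' @param chirality `"L"` or `"R"`.
#' @param structure_kind One of `"grid"`, `"npc"`, `"filament"`, `"custom"`.
#' @param structure_instance_id Integer instance label.
#'
#' @return An object of class `structure_model`.
#' @export
structure_model <- function(sites, species_id, chirality,
                            structure_kind = "custom",
                            structure_instance_id = 1L) {
  chirality <- match.arg(chirality, c("L", "R"))
  structure_kind <- match.arg(structure_kind,
                              c("grid", "npc", "filament", "custom"))
  sites <- tibble::as_tibble(sites)
  stopifnot(all(c("x", "y", "z") %in% names(sites)))
  if (nrow(sites) > 0 &&
      !all(is.finite(sites$x) & is.finite(sites$y) & is.finite(sites$z))) {
    stop("structure_model: site coordinates must be finite", call. = FALSE)
  }
  out <- list(
    sites = sites[, c("x", "y", "z")],
    species_id = as.integer(species_id),
    chirality = chirality,
    structure_kind = structure_kind,
    structure_instance_id = as.integer(structure_instance_id)
  )
  class(out) <- "structure_model"
  out
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model> %s #%d, species %d (%s), %d sites\n",
              x$structure_kind, x$structure_instance_id, x$species_id,
              x$chirality, nrow(x$sites)))
  invisible(x)
}

#' Rectangular DNA origami grid of docking sites
#'
#' Builds a `rows` x `cols` lattice of binding sites at the given pitch,
#' centered at the origin with z = 0. The default 4x3 grid at 15 nm pitch
#' is the 12-site origami benchmark; a 1x2 grid at 5 nm pitch is the
#' two-site high-resolution origami.
#'
#' @param rows,cols Lattice dimensions (>= 1).
#' @param pitch Site spacing in nm (> 0).
#' @param species_id,chirality,structure_instance_id See [structure_model()].
#' @return A `structure_model` with `rows * cols` sites.
#' @export
make_origami_grid <- function(rows = 4L, cols = 3L, pitch = 15,
                              species_id = 1L, chirality = "R",
                              structure_instance_id = 1L) {
  if (!is.numeric(pitch) || length(pitch) != 1L || !is.finite(pitch) ||
      pitch <= 0) {
    stop("make_origami_grid: `pitch` must be a positive number",
         call. = FALSE)
  }
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (rows < 1L || cols < 1L) {
    stop("make_origami_grid: `rows` and `cols` must be >= 1", call. = FALSE)
  }
  gx <- (seq_len(cols) - (cols + 1) / 2) * pitch
  gy <- (seq_len(rows) - (rows + 1) / 2) * pitch
  sites <- expand.grid(x = gx, y = gy, KEEP.OUT.ATTRS = FALSE)
  sites$z <- 0
  structure_model(sites, species_id, chirality, "grid",
                  structure_instance_id)
}

#' Nuclear-pore (Nup96) reference standard
#'
#' Two parallel 8-fold-symmetric rings of binding sites. Each ring carries
#' `copies_per_ring / 2` corners; each corner holds two sites separated by
#' `pair_spacing` along the ring tangent, mimicking the Nup96 corner pairs
#' (~14.3 nm). The rings sit at z = +/- `ring_separation` / 2 (~50 nm
#' apart); the ring diameter defaults to the 107 nm literature value.
#'
#' @param ring_diameter Ring diameter, nm.
#' @param ring_separation Axial distance between the two rings, nm.
#' @param pair_spacing Within-corner site separation, nm.
#' @param copies_per_ring Sites per ring; must be even (sites come in
#'   corner pairs). Default 16 (8 corners x 2).
#' @param species_id,chirality,structure_instance_id See [structure_model()].
#' @return A `structure_model` with `copies_per_ring * 2` sites.
#' @export
make_npc <- function(ring_diameter = 107, ring_separation = 50,
                     pair_spacing = 14.3, copies_per_ring = 16L,
                     species_id = 1L, chirality = "L",
                     structure_instance_id = 1L) {
  for (nm in c("ring_diameter", "ring_separation")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("make_npc: `", nm, "` must be a positive number", call. = FALSE)
    }
  }
  if (pair_spacing < 0) stop("make_npc: `pair_spacing` must be >= 0",
                             call. = FALSE)
  copies_per_ring <- as.integer(copies_per_ring)
  if (copies_per_ring < 2L || copies_per_ring %% 2L != 0L) {
    stop("make_npc: `copies_per_ring` must be a positive even count ",
         "(sites come in corner pairs)", call. = FALSE)
  }
  n_corners <- copies_per_ring %/% 2L
  r <- ring_diameter / 2
  theta <- 2 * pi * (seq_len(n_corners) - 1) / n_corners
  # Corner centers and tangent directions; a corner's two sites sit at
  # +/- pair_spacing/2 along the tangent.
  cx <- r * cos(theta); cy <- r * sin(theta)
  tx <- -sin(theta); ty <- cos(theta)
  one_ring <- function(zlev) {
    tibble::tibble(
      x = c(cx - tx * pair_spacing / 2, cx + tx * pair_spacing / 2),
      y = c(cy - ty * pair_spacing / 2, cy + ty * pair_spacing / 2),
      z = zlev
    )
  }
  sites <- rbind(one_ring(-ring_separation / 2), one_ring(ring_separation / 2))
  structure_model(sites, species_id, chirality, "npc",
                  structure_instance_id)
}

#' Filament (tubulin-like) cylinder model
#'
#' Places sites uniformly at random on the surface of a straight cylinder
#' of the given radius about the x axis, centered at the origin. The site
#' count is Poisson with mean `sites_per_um * length / 1000`. The default
#' 15 nm radius reproduces the ~30 nm effective diameter of
#' antibody-labeled microtubules.
#'
#' @param length Filament length, nm (0 gives a single cross-section).
#' @param radius Cylinder radius, nm (> 0).
#' @param sites_per_um Linear site density per micrometre.
#' @param species_id,chirality,structure_instance_id See [structure_model()].
#' @return A `structure_model`; empty (with a warning) if the density is 0.
#' @export
make_filament <- function(length = 2000, radius = 15, sites_per_um = 250,
                          species_id = 1L, chirality = "L",
                          structure_instance_id = 1L) {
  if (!is.numeric(radius) || radius <= 0) {
    stop("make_filament: `radius` must be positive", call. = FALSE)
  }
  if (length < 0 || sites_per_um < 0) {
    stop("make_filament: `length` and `sites_per_um` must be >= 0",
         call. = FALSE)
  }
  mu <- sites_per_um * length / 1000
  n <- if (length == 0) max(1L, as.integer(sites_per_um)) else stats::rpois(1, mu)
  if (n == 0 || sites_per_um == 0) {
    warning("make_filament: zero site density, returning empty structure")
    sites <- tibble::tibble(x = numeric(0), y = numeric(0), z = numeric(0))
    return(structure_model(sites, species_id, chirality, "filament",
                           structure_instance_id))
  }
  ax <- if (length == 0) rep(0, n) else stats::runif(n, -length / 2, length / 2)
  phi <- stats::runif(n, 0, 2 * pi)
  sites <- tibble::tibble(x = ax, y = radius * cos(phi), z = radius * sin(phi))
  structure_model(sites, species_id, chirality, "filament",
                  structure_instance_id)
}

#' Translate a structure model
#'
#' @param model A `structure_model`.
#' @param dx,dy,dz Offsets in nm.
#' @return The shifted `structure_model`.
#' @export
shift_structure <- function(model, dx = 0, dy = 0, dz = 0) {
  stopifnot(inherits(model, "structure_model"))
  model$sites$x <- model$sites$x + dx
  model$sites$y <- model$sites$y + dy
  model$sites$z <- model$sites$z + dz
  model
}

#' Arrange structures on a lattice inside the field of view
#'
#' Deterministically places a list of (origin-centered) structures on a
#' near-square lattice within the configured field of view, leaving a
#' margin so that picks do not clip the FOV edge.
#'
#' @param models List of `structure_model`s.
#' @param config A [sim_config()].
#' @param margin_px Margin kept free at each FOV edge, pixels.
#' @return The list of shifted models (instance ids renumbered 1..n).
#' @export
place_structures <- function(models, config, margin_px = 4) {
  validate_sim_config(config)
  n <- length(models)
  if (n == 0) return(models)
  ncol_ <- ceiling(sqrt(n))
  nrow_ <- ceiling(n / ncol_)
  px <- config$pixel_size
  w <- (config$fov_width - 2 * margin_px) * px
  h <- (config$fov_height - 2 * margin_px) * px
  xs <- margin_px * px + (seq_len(ncol_) - 0.5) / ncol_ * w
  ys <- margin_px * px + (seq_len(nrow_) - 0.5) / nrow_ * h
  out <- vector("list", n)
  for (i in seq_len(n)) {
    r <- (i - 1) %/% ncol_ + 1
    c_ <- (i - 1) %% ncol_ + 1
    m <- shift_structure(models[[i]], xs[c_], ys[r])
    m$structure_instance_id <- i
    out[[i]] <- m
  }
  out
}

# True center of a placed structure, nm.
structure_center <- function(model) {
  c(x = mean(model$sites$x), y = mean(model$sites$y))
}
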