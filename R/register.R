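#' Track fiducials and estimate per-frame drift
#'
#' Fiducials are detected as persistent localization clusters: cells of a
#' coarse 2D histogram whose counts are a sizeable fraction of the frame
#' count seed candidates, adjacent candidate cells merge, and a candidate
#' is kept when its localizations appear in at least `min_presence` of all
#' frames (DNA-PAINT sites are sparse in time; gold beads are not). The
#' per-frame drift is the mean over fiducials of (position - fiducial mean
#' position), smoothed with a centered moving average, and has zero mean.
#'
#' @param table A `loc_table`.
#' @param min_presence Minimum fraction of frames a fiducial must appear
#'   in (default 0.8).
#' @param smooth_window Moving-average window, frames (default 100).
#' @param detect_bin_px Histogram bin for candidate detection, pixels.
#' @param search_radius_px Radius around a candidate centroid within which
#'   localizations are assigned to its track, pixels.
#' @return A `drift_trace`: tibble with `frame`, `dx`, `dy` (pixels), with
#'   attributes `n_fiducials`, `fiducial_centers` and `smooth_window`.
#' @export
track_fiducials <- function(table, min_presence = 0.8, smooth_window = 100L,
                            detect_bin_px = 2, search_radius_px = 3) {
  validate_loc_table(table)
  locs <- table$locs
  nf <- table$meta$n_frames
  if (nrow(locs) == 0) {
    stop("track_fiducials: empty table", call. = FALSE)
  }
  need <- min_presence * nf
  # Candidate cells: a fiducial contributes ~n_frames localizations spread
  # over a handful of cells, far above any transiently binding site.
  cx <- floor(locs$x / detect_bin_px)
  cy <- floor(locs$y / detect_bin_px)
  key <- paste(cx, cy)
  counts <- table(key)
  cand <- names(counts)[counts >= need / 4]
  if (length(cand) == 0) {
    stop("track_fiducials: no persistent emitter found (no cluster present ",
         "in >= ", min_presence, " of frames); fiducial-free drift ",
         "correction is not supported", call. = FALSE)
  }
  cc <- do.call(rbind, lapply(strsplit(cand, " "), as.numeric))
  # Merge adjacent candidate cells (Chebyshev distance 1).
  adj <- which(outer(cc[, 1], cc[, 1], function(a, b) abs(a - b) <= 1) &
                 outer(cc[, 2], cc[, 2], function(a, b) abs(a - b) <= 1),
               arr.ind = TRUE)
  adj <- adj[adj[, 1] < adj[, 2], , drop = FALSE]
  comp <- connected_components(nrow(cc),
                               list(i = adj[, 1], j = adj[, 2]))
  centers <- do.call(rbind, lapply(split(seq_len(nrow(cc)), comp),
    function(ix) {
      members <- key %in% cand[ix]
      c(mean(locs$x[members]), mean(locs$y[members]))
    }))
  # Build tracks, keep the persistent ones.
  tracks <- list()
  for (k in seq_len(nrow(centers))) {
    d2 <- (locs$x - centers[k, 1])^2 + (locs$y - centers[k, 2])^2
    m <- which(d2 <= search_radius_px^2)
    if (length(unique(locs$frame[m])) >= need) {
      tracks[[length(tracks) + 1L]] <- m
    }
  }
  if (length(tracks) == 0) {
    stop("track_fiducials: no persistent emitter found (no cluster present ",
         "in >= ", min_presence, " of frames); fiducial-free drift ",
         "correction is not supported", call. = FALSE)
  }
  dx_sum <- numeric(nf); dy_sum <- numeric(nf); n_at <- numeric(nf)
  fid_centers <- matrix(NA_real_, length(tracks), 2)
  for (k in seq_along(tracks)) {
    m <- tracks[[k]]
    ckx <- mean(locs$x[m]); cky <- mean(locs$y[m])
    # One position per frame: the localization nearest the track centroid.
    # This keeps the track immune to transient binding events of nearby
    # structures that fall inside the search radius.
    d2 <- (locs$x[m] - ckx)^2 + (locs$y[m] - cky)^2
    o <- order(locs$frame[m], d2)
    sel <- m[o][!duplicated(locs$frame[m][o])]
    fidx <- locs$frame[sel] + 1L
    px_f <- locs$x[sel]; py_f <- locs$y[sel]
    fid_centers[k, ] <- c(mean(px_f), mean(py_f))
    dx_sum[fidx] <- dx_sum[fidx] + (px_f - fid_centers[k, 1])
    dy_sum[fidx] <- dy_sum[fidx] + (py_f - fid_centers[k, 2])
    n_at[fidx] <- n_at[fidx] + 1
  }
  have <- n_at > 0
  dx <- rep(NA_real_, nf); dy <- rep(NA_real_, nf)
  dx[have] <- dx_sum[have] / n_at[have]
  dy[have] <- dy_sum[have] / n_at[have]
  if (!all(have)) {
    frames_all <- seq_len(nf)
    dx <- stats::approx(frames_all[have], dx[have], xout = frames_all,
                        rule = 2)$y
    dy <- stats::approx(frames_all[have], dy[have], xout = frames_all,
                        rule = 2)$y
  }
  dx <- running_mean(dx, smooth_window)
  dy <- running_mean(dy, smooth_window)
  dx <- dx - mean(dx); dy <- dy - mean(dy)
  out <- tibble::tibble(frame = 0:(nf - 1L), dx = dx, dy = dy)
  attr(out, "n_fiducials") <- length(tracks)
  attr(out, "fiducial_centers") <- fid_centers
  attr(out, "smooth_window") <- as.integer(smooth_window)
  class(out) <- c("drift_trace", class(out))
  out
}

# Centered moving average with shrinking windows at the edges.
running_mean <- function(v, w) {
  w <- as.integer(w)
  if (w <= 1) return(v)
  n <- length(v)
  h <- w %/% 2L
  cs <- c(0, cumsum(v))
  lo <- pmax(1L, seq_len(n) - h)
  hi <- pmin(n, seq_len(n) + h)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Remove drift from a localization table
#'
#' Shifts every localization by minus the drift of its frame and flags the
#' metadata as drift-corrected.
#'
#' @param table A `loc_table`.
#' @param trace A drift trace (tibble `frame`, `dx`, `dy` in pixels) from
#'   [track_fiducials()] or the simulator.
#' @return The corrected `loc_table`.
#' @export
undrift <- function(table, trace) {
  validate_loc_table(table)
  if (nrow(trace) != table$meta$n_frames) {
    stop("undrift: drift trace has ", nrow(trace), " frames but the table ",
         "has n_frames = ", table$meta$n_frames, call. = FALSE)
  }
  idx <- table$locs$frame + 1L
  table$locs$x <- table$locs$x - trace$dx[idx]
  table$locs$y <- table$locs$y - trace$dy[idx]
  table$meta$drift_corrected <- TRUE
  table
}

# Render a localization table as a 2D count histogram at bin_nm, with an
# optional separable Gaussian blur (sigma in bins) to stabilize subpixel
# correlation peaks. Returns a matrix indexed [x_bin, y_bin].
render_image <- function(table, bin_nm = 65, blur_sigma = 2,
                         origin_px = c(0, 0), extent_px = NULL) {
  px <- table$meta$pixel_size
  if (is.null(extent_px)) extent_px <- c(table$meta$width, table$meta$height)
  bin_px <- bin_nm / px
  nx <- max(1L, as.integer(ceiling(extent_px[1] / bin_px)))
  ny <- max(1L, as.integer(ceiling(extent_px[2] / bin_px)))
  ix <- floor((table$locs$x - origin_px[1]) / bin_px) + 1L
  iy <- floor((table$locs$y - origin_px[2]) / bin_px) + 1L
  keep <- ix >= 1L & ix <= nx & iy >= 1L & iy <= ny
  img <- matrix(tabulate(ix[keep] + (iy[keep] - 1L) * nx, nbins = nx * ny),
                nrow = nx, ncol = ny)
  if (blur_sigma > 0) img <- gauss_blur(img, blur_sigma)
  img
}

gauss_blur <- function(img, sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  pad <- function(m, n) rbind(matrix(0, n, ncol(m)), m,
                              matrix(0, n, ncol(m)))
  conv1 <- function(m) {
    # filter() along columns; pad to keep full length, then trim.
    p <- pad(m, r)
    f <- stats::filter(p, k, sides = 2)
    f[(r + 1):(r + nrow(m)), , drop = FALSE]
  }
  t(conv1(t(conv1(img))))
}

# Circular FFT cross-correlation peak with 3-point parabolic subpixel
# interpolation per axis. Returns lag (in bins) that maps `mov` onto
# `ref` when *added* to mov's coordinates, plus the normalized score.
xcorr_peak <- function(ref, mov) {
  a <- ref - mean(ref)
  b <- mov - mean(mov)
  fa <- stats::fft(a)
  fb <- stats::fft(b)
  cc <- Re(stats::fft(fa * Conj(fb), inverse = TRUE)) / length(a)
  pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  nx <- nrow(cc); ny <- ncol(cc)
  wrap <- function(i, n) ((i - 1L) %% n) + 1L
  para <- function(cm, c0, cp) {
    # Gaussian (log-parabolic) interpolation where possible -- exact for
    # the Gaussian-blurred peaks we render; 3-point parabola otherwise.
    if (cm > 0 && c0 > 0 && cp > 0) {
      lm_ <- log(cm); l0 <- log(c0); lp <- log(cp)
      den <- lm_ - 2 * l0 + lp
      if (den < 0) return(max(-0.5, min(0.5, 0.5 * (lm_ - lp) / den)))
    }
    den <- cm - 2 * c0 + cp
    if (den == 0) return(0)
    max(-0.5, min(0.5, 0.5 * (cm - cp) / den))
  }
  ddx <- para(cc[wrap(pk[1] - 1L, nx), pk[2]], cc[pk[1], pk[2]],
              cc[wrap(pk[1] + 1L, nx), pk[2]])
  ddy <- para(cc[pk[1], wrap(pk[2] - 1L, ny)], cc[pk[1], pk[2]],
              cc[pk[1], wrap(pk[2] + 1L, ny)])
  lag <- function(i, n) if (i - 1L > n / 2) i - 1L - n else i - 1L
  score <- max(cc) / sqrt(sum(a^2) * sum(b^2))
  list(dx = lag(pk[1], nx) + ddx, dy = lag(pk[2], ny) + ddy,
       score = score)
}

#' Align one localization channel onto another by cross-correlation
#'
#' Both tables are rendered as 2D histograms at `render_bin` (lightly
#' blurred), the normalized cross-correlation peak is located with
#' 3-point parabolic subpixel interpolation per axis, and the resulting
#' shift maps `moving` onto `reference` (add it to the moving
#' coordinates, e.g. via [apply_shift()]).
#'
#' @param reference,moving `loc_table`s sharing a coordinate system (both
#'   should contain the fiducials used for registration).
#' @param render_bin Rendering bin, nm (default 65 = half a pixel at
#'   130 nm).
#' @return A `shift`: list with `dx`, `dy` (pixels) and `score` (peak
#'   normalized correlation, in `[-1, 1]`).
#' @export
align_channels <- function(reference, moving, render_bin = 65) {
  validate_loc_table(reference)
  validate_loc_table(moving)
  if (nrow(reference$locs) == 0 || nrow(moving$locs) == 0) {
    stop("align_channels: empty localization table", call. = FALSE)
  }
  img_r <- render_image(reference, render_bin)
  img_m <- render_image(moving, render_bin)
  pk <- xcorr_peak(img_r, img_m)
  bin_px <- render_bin / reference$meta$pixel_size
  out <- list(dx = pk$dx * bin_px, dy = pk$dy * bin_px, score = pk$score)
  class(out) <- "shift"
  out
}

#' @export
print.shift <- function(x, ...) {
  cat(sprintf("<shift> dx = %.4f px, dy = %.4f px (score %.3f)\n",
              x$dx, x$dy, x$score))
  invisible(x)
}

#' Apply a shift to a localization table
#'
#' @param table A `loc_table`.
#' @param shift A `shift` (or list/vector with `dx`, `dy` in pixels).
#' @return The shifted table.
#' @export
apply_shift <- function(table, shift) {
  table$locs$x <- table$locs$x + shift$dx
  table$locs$y <- table$locs$y + shift$dy
  table
}

#' Register a rectangular grid of tiles by overlap cross-correlation
#'
#' Tiles are first laid out at their nominal grid offsets (tile size minus
#' overlap); each tile's residual shift is then estimated by rendering the
#' pairwise overlap strip of a registration channel and locating the
#' cross-correlation peak. Alignment is chained from the top-left
#' reference tile: tiles of the first row register to their left
#' neighbor, tiles of the first column to their upper neighbor, and inner
#' tiles to the tile above them (for a 2x2 layout: top-left anchors
#' top-right and bottom-left; bottom-right chains to top-right). The
#' per-tile shift is meant to be applied identically to all channels of
#' that tile.
#'
#' @param tiles List (one entry per tile) of lists of per-channel
#'   `loc_table`s; a bare `loc_table` is treated as a single channel. Tile
#'   coordinates are local (each tile starts at 0).
#' @param layout Data frame with columns `tile` (index into `tiles`),
#'   `row`, `col` (1-based grid position).
#' @param overlap_um Overlap between adjacent tiles, micrometres (> 0).
#' @param render_bin Rendering bin for the correlation, nm.
#' @param registration_channel Channel used to estimate the shifts.
#' @param min_score Normalized-correlation score below which the
#'   refinement is distrusted and the coarse (nominal) offset is kept,
#'   with a warning.
#' @return A tibble with one row per tile: `tile`, `row`, `col`,
#'   `offset_x`, `offset_y` (nominal layout offsets, px), `dx`, `dy`
#'   (refined residual shifts, px) and `score`.
#' @export
stitch_tiles <- function(tiles, layout, overlap_um, render_bin = 65,
                         registration_channel = 1L, min_score = 0.05) {
  if (overlap_um <= 0) stop("stitch_tiles: `overlap_um` must be > 0",
                            call. = FALSE)
  layout <- as.data.frame(layout)
  stopifnot(all(c("tile", "row", "col") %in% names(layout)))
  get_chan <- function(t) {
    tl <- tiles[[t]]
    if (inherits(tl, "loc_table")) tl else tl[[registration_channel]]
  }
  ref0 <- get_chan(layout$tile[layout$row == 1 & layout$col == 1])
  px <- ref0$meta$pixel_size
  w <- ref0$meta$width; h <- ref0$meta$height
  ov_px <- overlap_um * 1000 / px
  layout$offset_x <- (layout$col - 1) * (w - ov_px)
  layout$offset_y <- (layout$row - 1) * (h - ov_px)
  layout$dx <- 0; layout$dy <- 0; layout$score <- NA_real_
  # Chain parent: NULL for the reference, otherwise (row, col) of the tile
  # this one registers against.
  parent_of <- function(r, c_) {
    if (r == 1 && c_ == 1) return(NULL)
    if (r == 1) return(c(1, c_ - 1))
    if (c_ == 1) return(c(r - 1, 1))
    c(r - 1, c_)
  }
  ord <- order(layout$row + layout$col, layout$row)
  for (k in ord) {
    r <- layout$row[k]; c_ <- layout$col[k]
    par <- parent_of(r, c_)
    if (is.null(par)) next
    kp <- which(layout$row == par[1] & layout$col == par[2])
    ref <- get_chan(layout$tile[kp])
    mov <- get_chan(layout$tile[k])
    # Global coordinates: parent with its resolved shift, moving tile at
    # its nominal offset.
    ref <- apply_shift(ref, list(dx = layout$offset_x[kp] + layout$dx[kp],
                                 dy = layout$offset_y[kp] + layout$dy[kp]))
    mov <- apply_shift(mov, list(dx = layout$offset_x[k],
                                 dy = layout$offset_y[k]))
    # Overlap rectangle of the two nominal tile extents.
    x0 <- max(layout$offset_x[kp], layout$offset_x[k])
    x1 <- min(layout$offset_x[kp] + w, layout$offset_x[k] + w)
    y0 <- max(layout$offset_y[kp], layout$offset_y[k])
    y1 <- min(layout$offset_y[kp] + h, layout$offset_y[k] + h)
    crop <- function(tab) {
      sel <- tab$locs$x >= x0 & tab$locs$x <= x1 &
             tab$locs$y >= y0 & tab$locs$y <= y1
      tab$locs <- tab$locs[sel, , drop = FALSE]
      tab
    }
    ref_c <- crop(ref); mov_c <- crop(mov)
    if (nrow(ref_c$locs) == 0 || nrow(mov_c$locs) == 0) {
      warning("stitch_tiles: empty overlap between tiles (", par[1], ",",
              par[2], ") and (", r, ",", c_, "); keeping coarse offset")
      layout$dx[k] <- layout$dx[kp]; layout$dy[k] <- layout$dy[kp]
      next
    }
    ext <- c(x1 - x0, y1 - y0)
    img_r <- render_image(ref_c, render_bin, origin_px = c(x0, y0),
                          extent_px = ext)
    img_m <- render_image(mov_c, render_bin, origin_px = c(x0, y0),
                          extent_px = ext)
    pk <- xcorr_peak(img_r, img_m)
    bin_px <- render_bin / px
    if (pk$score < min_score) {
      warning("stitch_tiles: low correlation score (", round(pk$score, 3),
              ") in overlap of tiles (", par[1], ",", par[2], ") and (",
              r, ",", c_, "); keeping coarse offset")
      layout$dx[k] <- layout$dx[kp]; layout$dy[k] <- layout$dy[kp]
      layout$score[k] <- pk$score
      next
    }
    layout$dx[k] <- pk$dx * bin_px
    layout$dy[k] <- pk$dy * bin_px
    layout$score[k] <- pk$score
  }
  tibble::as_tibble(layout[, c("tile", "row", "col", "offset_x", "offset_y",
                               "dx", "dy", "score")])
}

#' Assemble stitched tiles into per-channel mosaics
#'
#' Applies each tile's layout offset plus refined shift (from
#' [stitch_tiles()]) identically to all channels of that tile and merges
#' the tiles per channel.
#'
#' @param tiles As in [stitch_tiles()].
#' @param shifts Output of [stitch_tiles()].
#' @return A list of merged `loc_table`s, one per channel.
#' @export
assemble_tiles <- function(tiles, shifts) {
  first <- tiles[[shifts$tile[1]]]
  if (inherits(first, "loc_table")) {
    tiles <- lapply(tiles, function(t) list(t))
    first <- tiles[[shifts$tile[1]]]
  }
  n_chan <- length(first)
  lapply(seq_len(n_chan), function(ch) {
    parts <- lapply(seq_len(nrow(shifts)), function(k) {
      tab <- tiles[[shifts$tile[k]]][[ch]]
      tab <- apply_shift(tab, list(dx = shifts$offset_x[k] + shifts$dx[k],
                                   dy = shifts$offset_y[k] + shifts$dy[k]))
      tab$locs
    })
    out <- tiles[[shifts$tile[1]]][[ch]]
    out$locs <- do.call(rbind, parts)
    out$meta$width <- as.integer(ceiling(max(shifts$offset_x) + out$meta$width))
    out$meta$height <- as.integer(ceiling(max(shifts$offset_y) + out$meta$height))
    out
  })
}
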