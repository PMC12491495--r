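#' Simulate two-state binding kinetics for one structure
#'
#' Each docking site is an independent telegraph process alternating
#' exponentially distributed dark intervals (mean `1 / (k_on * c)`) and
#' bright intervals (mean `1 / k_off`). The process starts dark with a
#' fresh exponential residual (the stationary choice for a memoryless dark
#' state), so dark-time estimates carry no transient bias. Sites are
#' independently retained with probability `labeling_efficiency` before
#' simulation.
#'
#' @param model A `structure_model`.
#' @param config A [sim_config()]; `imager_concentration` is in pM.
#' @param rate_scale Multiplier on the association rate (used for
#'   off-target/crosstalk binding; 0 disables binding entirely).
#' @param apply_labeling Whether to draw site retention here (disable when
#'   retention has already been decided upstream, e.g. per exchange
#'   experiment).
#' @return A list of emitter traces, one per retained site: each a list
#'   with `site_index` and `intervals`, a 2-column matrix of
#'   `(t_start, t_end)` seconds clipped to the acquisition.
#' @export
simulate_blinking <- function(model, config, rate_scale = 1,
                              apply_labeling = TRUE) {
  validate_sim_config(config)
  stopifnot(inherits(model, "structure_model"))
  n_sites <- nrow(model$sites)
  if (n_sites == 0) return(list())
  retained <- if (apply_labeling) {
    which(stats::runif(n_sites) < config$labeling_efficiency)
  } else {
    seq_len(n_sites)
  }
  if (length(retained) == 0 || rate_scale <= 0) {
    return(lapply(retained, function(i) {
      list(site_index = i,
           intervals = matrix(numeric(0), ncol = 2,
                              dimnames = list(NULL, c("t_start", "t_end"))))
    }))
  }
  t_total <- config$n_frames * config$exposure_time
  rate_on <- config$k_on * rate_scale * conc_molar(config$imager_concentration)
  mean_dark <- 1 / rate_on
  mean_bright <- 1 / config$k_off
  lapply(retained, function(i) {
    list(site_index = i,
         intervals = sample_intervals(t_total, mean_dark, mean_bright))
  })
}

# Alternating exponential dark/bright intervals covering [0, t_total],
# starting dark. Draws in batches sized from the expected cycle count.
sample_intervals <- function(t_total, mean_dark, mean_bright) {
  n_guess <- ceiling(t_total / (mean_dark + mean_bright)) + 1
  starts <- numeric(0); ends <- numeric(0)
  t <- 0
  repeat {
    n_batch <- max(16L, ceiling(1.5 * n_guess) + 4L *
                     ceiling(sqrt(n_guess)))
    dk <- stats::rexp(n_batch, 1 / mean_dark)
    br <- stats::rexp(n_batch, 1 / mean_bright)
    s <- t + cumsum(dk + br) - br
    e <- s + br
    starts <- c(starts, s); ends <- c(ends, e)
    t <- e[length(e)]
    if (t >= t_total) break
    n_guess <- max(1, ceiling((t_total - t) / (mean_dark + mean_bright)))
  }
  keep <- starts < t_total
  starts <- starts[keep]
  ends <- pmin(ends[keep], t_total)
  cbind(t_start = starts, t_end = ends)
}

#' Render localizations from emitter traces
#'
#' Discretizes bound intervals onto camera frames: a frame yields one
#' localization for a site if the bright interval covers at least
#' `min_on_fraction` of that frame's exposure (approximating detection
#' thresholding without simulating photons). Localizations are the true
#' site position plus isotropic Gaussian noise (`localization_precision_xy`
#' laterally, `localization_precision_z` axially). `x`/`y` are stored in
#' pixels, `z` in nm.
#'
#' @param traces Emitter traces from [simulate_blinking()].
#' @param model The `structure_model` the traces belong to (site positions
#'   in absolute nm coordinates).
#' @param config A [sim_config()].
#' @param round_label Optional round label recorded in the metadata.
#' @return A `loc_table`; its `locs` carry a `site` column (1-based index
#'   into `model$sites`) for ground-truth bookkeeping.
#' @export
render_localizations <- function(traces, model, config,
                                 round_label = NA_character_) {
  validate_sim_config(config)
  dt <- config$exposure_time
  thr <- config$min_on_fraction * dt
  frames_list <- vector("list", length(traces))
  sites_list <- vector("list", length(traces))
  for (k in seq_along(traces)) {
    tr <- traces[[k]]
    iv <- tr$intervals
    if (is.null(iv) || nrow(iv) == 0) next
    fr <- interval_frames(iv, dt, thr, config$n_frames)
    if (length(fr)) {
      frames_list[[k]] <- fr
      sites_list[[k]] <- rep.int(tr$site_index, length(fr))
    }
  }
  frame <- unlist(frames_list, use.names = FALSE)
  site <- unlist(sites_list, use.names = FALSE)
  if (is.null(frame)) {
    frame <- integer(0); site <- integer(0)
  }
  n <- length(frame)
  sx <- model$sites$x[site]; sy <- model$sites$y[site]
  sz <- model$sites$z[site]
  px <- config$pixel_size
  sxy <- config$localization_precision_xy
  locs <- tibble::tibble(
    frame = as.integer(frame),
    x = (sx + stats::rnorm(n, 0, sxy)) / px,
    y = (sy + stats::rnorm(n, 0, sxy)) / px,
    z = sz + stats::rnorm(n, 0, config$localization_precision_z),
    photons = stats::rpois(n, config$mean_photons),
    lpx = rep(sxy / px, n),
    lpy = rep(sxy / px, n),
    site = as.integer(site)
  )
  locs <- locs[order(locs$frame, locs$site), , drop = FALSE]
  loc_table(locs, n_frames = config$n_frames, width = config$fov_width,
            height = config$fov_height, pixel_size = px,
            exposure = dt, round_label = round_label)
}

# Frames (0-based) in which intervals yield a localization: overlap with
# the frame's exposure window must reach `thr` seconds. Intervals are
# non-overlapping, so no frame is produced twice by one site.
interval_frames <- function(iv, dt, thr, n_frames) {
  out <- vector("list", nrow(iv))
  for (r in seq_len(nrow(iv))) {
    t0 <- iv[r, 1]; t1 <- iv[r, 2]
    f0 <- max(0L, as.integer(floor(t0 / dt)))
    f1 <- min(n_frames - 1L, as.integer(ceiling(t1 / dt)) - 1L)
    if (f1 < f0) next
    f <- f0:f1
    ov <- pmin(t1, (f + 1) * dt) - pmax(t0, f * dt)
    out[[r]] <- f[ov >= thr - 1e-12]
  }
  unlist(out, use.names = FALSE)
}
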