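#' Link localizations into binding events
#'
#' Maximal runs of localization-containing frames become binding events;
#' gaps of at most `max_gap_frames` empty frames are bridged (bridged
#' frames count toward the event duration). The default gap of 1 tolerates
#' single missed frames from detection flicker on real data; simulated
#' data (which never drops frames inside an event) is analyzed with
#' `max_gap_frames = 0`.
#'
#' @param pick_table A `loc_table` restricted to one pick, or an integer
#'   vector of (0-based) frames.
#' @param max_gap_frames Largest bridged gap, frames.
#' @param exposure Seconds per frame; taken from the table metadata when
#'   omitted.
#' @return A tibble of events: `start_frame`, `end_frame` (inclusive),
#'   `n_frames`, `duration` (seconds, `(end - start + 1) * exposure`).
#' @export
link_events <- function(pick_table, max_gap_frames = 1L, exposure = NULL) {
  if (inherits(pick_table, "loc_table")) {
    if (is.null(exposure)) exposure <- pick_table$meta$exposure
    frames <- pick_table$locs$frame
  } else {
    frames <- pick_table
  }
  if (is.null(exposure) || is.na(exposure)) {
    stop("link_events: `exposure` is required (not present in metadata)",
         call. = FALSE)
  }
  f <- sort(unique(as.integer(frames)))
  if (length(f) == 0) {
    return(tibble::tibble(start_frame = integer(0), end_frame = integer(0),
                          n_frames = integer(0), duration = numeric(0)))
  }
  brk <- which(diff(f) > max_gap_frames + 1L)
  start <- f[c(1L, brk + 1L)]
  end <- f[c(brk, length(f))]
  tibble::tibble(start_frame = start, end_frame = end,
                 n_frames = end - start + 1L,
                 duration = (end - start + 1L) * exposure)
}

#' Mean bright and dark time of an event list
#'
#' The bright time is the mean event duration; the dark time is the mean
#' inter-event gap (previous end to next start, exclusive), both in
#' seconds. The partial dark stretches before the first and after the
#' last event are excluded. With fewer than two events the dark time is
#' undefined (`NA`, flagged).
#'
#' @param events Event tibble from [link_events()].
#' @param n_frames Acquisition length, frames (recorded in the output).
#' @param exposure Seconds per frame.
#' @return List with `tau_b`, `tau_d_raw` (seconds; `tau_d_raw` is `NA`
#'   when undefined), `n_events` and `dark_defined`.
#' @export
bright_dark_times <- function(events, n_frames, exposure) {
  n <- nrow(events)
  if (n == 0) {
    return(list(tau_b = NA_real_, tau_d_raw = NA_real_, n_events = 0L,
                dark_defined = FALSE))
  }
  tau_b <- mean(events$duration)
  if (n < 2) {
    return(list(tau_b = tau_b, tau_d_raw = NA_real_, n_events = n,
                dark_defined = FALSE))
  }
  gaps <- events$start_frame[-1] - events$end_frame[-n] - 1L
  list(tau_b = tau_b, tau_d_raw = mean(gaps) * exposure,
       n_events = as.integer(n), dark_defined = TRUE)
}

#' Normalize a dark time to the 100 pM single-site reference
#'
#' Per-pick (whole-structure) dark times shorten with imager concentration
#' and with the number of active sites in the pick. The normalized value
#' `tau_d_raw * (c / 100 pM) * n_sites` is the single-site dark time a
#' 100 pM measurement would give.
#'
#' @param tau_d_raw Mean per-pick dark time, seconds.
#' @param c_pM Imager concentration of the measurement, pM.
#' @param n_sites Site count used for normalization (detected sites for
#'   origami; expected labeled copies for nuclear pores, see
#'   [npc_site_normalization()]).
#' @return Normalized single-site dark time at 100 pM, seconds.
#' @export
normalize_dark <- function(tau_d_raw, c_pM, n_sites) {
  if (any(!is.finite(tau_d_raw)) || any(tau_d_raw <= 0)) {
    stop("normalize_dark: `tau_d_raw` must be positive", call. = FALSE)
  }
  if (any(c_pM <= 0) || any(n_sites < 1)) {
    stop("normalize_dark: `c_pM` must be > 0 and `n_sites` >= 1",
         call. = FALSE)
  }
  tau_d_raw * (c_pM / 100) * n_sites
}

#' Effective site count for nuclear-pore normalization
#'
#' Nup96 NPC picks are normalized by the expected number of labeled
#' copies: `copies * labeling_efficiency` (16 copies at ~50% labeling
#' gives 8), so the normalized dark time represents single-binding-site
#' kinetics.
#'
#' @param copies Nup96 copies per NPC contributing to one imaging round.
#' @param labeling_efficiency Fraction of copies carrying a docking strand.
#' @return Effective site count `n_eff`.
#' @export
npc_site_normalization <- function(copies = 16, labeling_efficiency = 0.5) {
  stopifnot(copies >= 1, labeling_efficiency > 0, labeling_efficiency <= 1)
  copies * labeling_efficiency
}

#' Kinetics summary with normalization and rates
#'
#' @param tau_b Mean bright time, s.
#' @param tau_d_raw Mean per-pick dark time, s.
#' @param c_pM Imager concentration, pM.
#' @param n_sites Normalization site count.
#' @param n_picks Number of picks entering the means.
#' @return A `kinetics_summary` list with `tau_b`, `tau_d_raw`, `c_pM`,
#'   `n_sites`, `tau_d_norm`, `k_off` (1/s), `k_on` (1/(M s)), `n_picks`.
#' @export
kinetics_summary <- function(tau_b, tau_d_raw, c_pM, n_sites,
                             n_picks = NA_integer_) {
  tau_d_norm <- normalize_dark(tau_d_raw, c_pM, n_sites)
  out <- list(tau_b = tau_b, tau_d_raw = tau_d_raw, c_pM = c_pM,
              n_sites = n_sites, tau_d_norm = tau_d_norm,
              k_off = 1 / tau_b,
              k_on = 1 / (tau_d_norm * conc_molar(100)),
              n_picks = n_picks)
  class(out) <- "kinetics_summary"
  out
}

#' @export
print.kinetics_summary <- function(x, ...) {
  cat(sprintf(paste0(
    "<kinetics_summary> tau_b = %.3f s, tau_d(raw) = %.3f s @ %g pM x %g ",
    "sites\n  tau_d(100 pM, single site) = %.2f s; k_off = %.3f /s, ",
    "k_on = %.3g /(M s); %s picks\n"),
    x$tau_b, x$tau_d_raw, x$c_pM, x$n_sites, x$tau_d_norm, x$k_off,
    x$k_on, format(x$n_picks)))
  invisible(x)
}

#' Invert a kinetics summary to rate constants
#'
#' `k_off = 1 / tau_b`; `k_on = 1 / (tau_d_norm * 100 pM)` with the
#' reference concentration expressed in molar (1e-10 M).
#'
#' @param summary A `kinetics_summary` (or any list with `tau_b` and
#'   `tau_d_norm`).
#' @return List with `k_off` (1/s) and `k_on` (1/(M s)).
#' @export
estimate_rates <- function(summary) {
  if (is.null(summary$tau_b) || is.null(summary$tau_d_norm) ||
      !is.finite(summary$tau_b) || !is.finite(summary$tau_d_norm) ||
      summary$tau_b <= 0 || summary$tau_d_norm <= 0) {
    stop("estimate_rates: `tau_b` and `tau_d_norm` must be positive",
         call. = FALSE)
  }
  list(k_off = 1 / summary$tau_b,
       k_on = 1 / (summary$tau_d_norm * conc_molar(100)))
}

#' Wall time of a sequential multiplexed experiment
#'
#' `total = n_targets * t_round_min + n_exchanges * t_exchange_min`. With
#' the benchmark inputs (13 targets at 40 min per full field of view and
#' 12 two-minute buffer exchanges) this gives 544 min.
#'
#' @param n_targets Number of sequentially imaged targets.
#' @param t_round_min Acquisition time per target, minutes.
#' @param n_exchanges Number of buffer exchanges between rounds.
#' @param t_exchange_min Time per buffer exchange, minutes.
#' @return Total experiment time in minutes.
#' @export
experiment_time <- function(n_targets, t_round_min, n_exchanges,
                            t_exchange_min) {
  stopifnot(n_targets >= 0, n_exchanges >= 0, t_round_min >= 0,
            t_exchange_min >= 0)
  n_targets * t_round_min + n_exchanges * t_exchange_min
}

#' Pick-level kinetics extraction
#'
#' Runs the per-pick kinetics procedure over a list of picked
#' localization tables: events are linked per pick for the dark times
#' (whole-structure gaps), while bright times are linked within each
#' accepted cluster (single site), so that simultaneous events at
#' different sites of one structure do not merge into artificially long
#' bright events. Pick-level means are averaged unweighted across picks,
#' mirroring per-structure extraction.
#'
#' @param picks List of `loc_table`s (one per picked structure).
#' @param c_pM Imager concentration of the measurement, pM.
#' @param n_sites Normalization site count; `"detected"` (default) uses
#'   the mean accepted-cluster count over picks, a number uses it as-is
#'   (e.g. [npc_site_normalization()] output).
#' @param max_gap_frames Event-linking gap (frames).
#' @param cluster_radius,min_locs Clustering parameters for site
#'   detection (see [cluster_locs()]).
#' @param frame_filter Apply [frame_analysis_filter()] to detected sites.
#' @return A `kinetics_summary`; also carries `site_count_mean` (mean
#'   detected accepted sites per pick).
#' @export
extract_kinetics <- function(picks, c_pM, n_sites = "detected",
                             max_gap_frames = 0L, cluster_radius = 6.5,
                             min_locs = 5L, frame_filter = TRUE) {
  stopifnot(length(picks) > 0)
  exposure <- picks[[1]]$meta$exposure
  n_frames <- picks[[1]]$meta$n_frames
  tau_b_pick <- rep(NA_real_, length(picks))
  tau_d_pick <- rep(NA_real_, length(picks))
  sites_pick <- rep(NA_real_, length(picks))
  for (k in seq_along(picks)) {
    p <- picks[[k]]
    if (nrow(p$locs) == 0) next
    cs <- cluster_locs(p, radius = cluster_radius, min_locs = min_locs)
    if (frame_filter) cs <- apply_frame_analysis(cs, p)
    sites_pick[k] <- count_sites(cs)
    # Dark: whole-pick gaps.
    ev_pick <- link_events(p, max_gap_frames, exposure)
    bd <- bright_dark_times(ev_pick, n_frames, exposure)
    if (bd$dark_defined) tau_d_pick[k] <- bd$tau_d_raw
    # Bright: per accepted cluster.
    acc <- which(cs$clusters$accepted)
    if (length(acc)) {
      durs <- unlist(lapply(acc, function(ci) {
        link_events(p$locs$frame[cs$members[[ci]]], max_gap_frames,
                    exposure)$duration
      }), use.names = FALSE)
      if (length(durs)) tau_b_pick[k] <- mean(durs)
    }
  }
  tau_b <- mean(tau_b_pick, na.rm = TRUE)
  tau_d_raw <- mean(tau_d_pick, na.rm = TRUE)
  site_mean <- mean(sites_pick[sites_pick > 0], na.rm = TRUE)
  n_norm <- if (identical(n_sites, "detected")) site_mean else n_sites
  out <- kinetics_summary(tau_b, tau_d_raw, c_pM, n_norm,
                          n_picks = sum(!is.na(tau_d_pick)))
  out$site_count_mean <- site_mean
  out
}

#' Exponential-tail rate fit (cross-check utility)
#'
#' Mean-based dwell-time estimators are the primary path; this utility
#' fits the exponential tail of a duration sample (memorylessness: the
#' mean excess over a quantile threshold equals 1/rate) as an independent
#' sanity check against discretization artifacts near one frame.
#'
#' @param durations Dwell times, seconds.
#' @param q Lower quantile discarded before the mean-excess fit.
#' @return Estimated rate, 1/s.
#' @export
fit_exponential_tail <- function(durations, q = 0.25) {
  stopifnot(length(durations) >= 10)
  thr <- stats::quantile(durations, q, names = FALSE)
  tail_d <- durations[durations > thr]
  1 / (mean(tail_d) - thr)
}
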