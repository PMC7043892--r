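#' Run the standard tracking pipeline on a synthetic preset
#'
#' Generates the preset movie, applies the preset's substack convention
#' (e.g. the 20 s interval for slow clusters), temporal-median background
#' subtraction, LoG detection and LAP linking with the preset's gates, and
#' the minimum-displacement filter where the preset defines one. This is the
#' measurement side of the generation-recovery experiments.
#'
#' @param name preset name (see [ww_presets()]).
#' @param seed integer seed.
#' @param overrides optional preset overrides (see [generate_preset()]).
#' @param min_spots minimum spots per track for a track to enter speed
#'   summaries; short fragments double-count fast particles and carry the
#'   largest localization-jitter variance.
#' @return list with `tracks`, `stats` (per-track, filtered), `truth`,
#'   `movie` (the processed substack), `mean_speed` (mean over tracks of the
#'   jitter-corrected MSD speed; see [track_stats()]), `n_tracks`.
#' @export
track_preset <- function(name, seed, overrides = NULL, min_spots = NULL) {
  res <- generate_preset(name, seed, overrides)
  tk <- res$preset$tracking
  if (is.null(tk)) stop("preset '", name, "' has no tracking convention")
  min_spots <- min_spots %||% tk$min_spots %||% 10L
  m <- res$movie
  if (tk$stride > 1L) m <- crop_substack(m, frame_stride = tk$stride)
  mw <- min(tk$median_window, n_frames(m) - (1 - n_frames(m) %% 2L))
  if (mw %% 2L == 0L) mw <- mw - 1L
  # detection runs on unclamped residuals: clamping halves the background
  # noise distribution and wrecks the robust (MAD-based) response threshold
  if (mw >= 3L) m <- temporal_median_subtract(m, mw, clamp_negative = FALSE)
  spots <- detect_spots_movie(m, spot_params())
  tracks <- link_tracks(spots, link_params(max_link_px = tk$link_px,
                                           max_gap_frames = tk$gap_frames,
                                           max_gap_px = tk$gap_px))
  if (!is.null(tk$min_disp_px))
    tracks <- filter_min_displacement(tracks, min_disp_px = tk$min_disp_px,
                                      window_s = tk$window_s,
                                      frame_interval_s = m$frame_interval_s)
  st <- track_stats(tracks, m$pixel_size_um, m$frame_interval_s)
  st <- st[!is.na(st$msd_speed_um_s) & st$n_spots >= min_spots, ,
           drop = FALSE]
  list(tracks = tracks, stats = st, truth = res$truth, movie = m,
       mean_speed = if (nrow(st)) mean(st$msd_speed_um_s) else NA_real_,
       n_tracks = nrow(st))
}

#' Grand mean recovered speed over several seeds
#'
#' Pools the per-track jitter-corrected speeds of [track_preset()] runs
#' across seeds and returns their grand mean — the statistic compared
#' against the preset's programmed speed in the generation-recovery
#' experiments.
#'
#' @inheritParams track_preset
#' @param seeds integer vector of seeds.
#' @return `list(mean_speed_um_s, n_tracks, per_seed)`.
#' @export
preset_speed_recovery <- function(name, seeds, overrides = NULL,
                                  min_spots = NULL) {
  speeds <- c(); per_seed <- numeric(0)
  for (s in seeds) {
    r <- track_preset(name, s, overrides, min_spots)
    speeds <- c(speeds, r$stats$msd_speed_um_s)
    per_seed <- c(per_seed, r$mean_speed)
  }
  list(mean_speed_um_s = mean(speeds), n_tracks = length(speeds),
       per_seed = per_seed)
}

#' Ring-closure velocimetry recovery over several seeds
#'
#' Generates the contracting-ring preset, measures the max-intensity radius
#' versus time through the automated wound centroid and radial profile, and
#' fits the two-phase closure model; returns the recovered fast/slow speeds.
#'
#' @param seeds integer vector of seeds.
#' @param name ring preset name.
#' @param overrides optional preset overrides.
#' @return `list(v1_um_s, v2_um_s, ratio, fits, n)`: means over seeds and
#'   the individual fits.
#' @export
ring_recovery <- function(seeds, name = "ring_eb1", overrides = NULL) {
  v1 <- v2 <- numeric(0)
  fits <- list()
  n <- 0L
  for (s in seeds) {
    res <- generate_preset(name, s, overrides)
    trace <- ring_radius_trace(res$movie)
    fit <- two_phase_fit(trace$t_s, trace$r_max_um)
    v1 <- c(v1, fit$v1_um_s); v2 <- c(v2, fit$v2_um_s)
    fits[[as.character(s)]] <- fit
    n <- n + nrow(trace)
  }
  list(v1_um_s = mean(v1), v2_um_s = mean(v2), ratio = mean(v1) / mean(v2),
       fits = fits, n = n)
}
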