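#' Synthetic-movie presets encoding the measured epidermal dynamics
#'
#' Each preset bundles generator parameters, acquisition geometry
#' (0.08 um/px, the 100x spinning-disk configuration), noise, and the
#' tracking parameters appropriate for that regime. The dynamic parameters
#' are the reporter statistics measured in the wounded-epidermis study:
#'
#' \describe{
#'   \item{`eb1_unwounded`}{EB1 comets, 0.26 um/s (CV 0.10/0.26), 0.3 s/frame.}
#'   \item{`eb1_near_wound`}{EB1 comets near the wound, 0.16 um/s (CV
#'     0.06/0.16), moving toward the wound point.}
#'   \item{`rab11`}{RAB-11 recycling-endosome vesicles, 1.31 um/s (CV
#'     0.33/1.31), directed runs, 0.4 s/frame.}
#'   \item{`snf12_unwounded`}{mostly static SNF-12 clusters with a moving
#'     subpopulation at 0.017 um/s, 0.2 s/frame, analysed on a 20 s substack.}
#'   \item{`snf12_wounded`}{SNF-12 clusters converging on the wound at
#'     0.007 um/s, 20 s substack, 420 s displacement window.}
#'   \item{`ring_eb1`}{contracting EB1 ring: slow-phase closure 0.008 um/s
#'     with the fast phase 10 times faster.}
#' }
#'
#' The noise level gives a spot signal-to-noise ratio of about 5
#' (amplitude 52 over a background of 100 counts of Poisson noise plus
#' 3 counts of read noise).
#'
#' @return Named list of preset definitions.
#' @seealso [generate_preset()]
#' @export
ww_presets <- function() {
  px <- 0.08
  noise <- noise_params(photon_scale = 1, read_sigma = 3)
  amp <- 52; bg <- 100
  list(
    eb1_unwounded = list(
      kind = "comet",
      params = comet_params(speed_um_s = 0.26, speed_cv = 0.10 / 0.26,
                            n_comets_per_frame = 15, lifetime_frames = 20,
                            psf_sigma_px = 1, amplitude = amp,
                            direction_mode = "ap_biased"),
      geometry = movie_geometry(200, 200, 300, px, 0.3, background = bg,
                                background_texture_amp = 5),
      noise = noise,
      tracking = list(stride = 1L, link_px = 2, gap_frames = 1L, gap_px = 2,
                      min_disp_px = NULL, window_s = NULL, median_window = 31L)),
    eb1_near_wound = list(
      kind = "comet",
      params = comet_params(speed_um_s = 0.16, speed_cv = 0.06 / 0.16,
                            n_comets_per_frame = 15, lifetime_frames = 20,
                            psf_sigma_px = 1, amplitude = amp,
                            direction_mode = "toward_point",
                            target = c(100, 100)),
      geometry = movie_geometry(200, 200, 300, px, 0.3, background = bg,
                                background_texture_amp = 5),
      noise = noise, t0_wound = 1L,
      tracking = list(stride = 1L, link_px = 2, gap_frames = 1L, gap_px = 2,
                      min_disp_px = NULL, window_s = NULL, median_window = 31L)),
    rab11 = list(
      kind = "vesicle", duty_cycle = 1, frac_moving = 1,
      params = comet_params(speed_um_s = 1.31, speed_cv = 0.33 / 1.31,
                            n_comets_per_frame = 10, lifetime_frames = 15,
                            psf_sigma_px = 1, amplitude = amp,
                            direction_mode = "isotropic"),
      geometry = movie_geometry(200, 200, 300, px, 0.4, background = bg,
                                background_texture_amp = 5),
      noise = noise,
      # 1.31 um/s at 0.4 s/frame is 6.55 px/frame: the linking gate scales
      # with the expected step (the 2-px gate belongs to the EB1 regime)
      tracking = list(stride = 1L, link_px = 12, gap_frames = 1L, gap_px = 12,
                      min_disp_px = NULL, window_s = NULL, median_window = 31L)),
    snf12_unwounded = list(
      kind = "vesicle", duty_cycle = 1, frac_moving = 0.3, persistent = TRUE,
      params = comet_params(speed_um_s = 0.017, speed_cv = 0.005 / 0.017,
                            n_comets_per_frame = 40, lifetime_frames = 1e6,
                            psf_sigma_px = 1.2, amplitude = amp,
                            direction_mode = "isotropic"),
      # a 5 min pre-wound acquisition: long enough for the 120 s
      # displacement window, short enough that movers (~80 px of travel)
      # rarely exit the field first
      geometry = movie_geometry(140, 140, 1501, px, 0.2, background = bg,
                                background_texture_amp = 5),
      noise = noise,
      # min_spots 6 = 120 s of track on the 20 s substack, matching the
      # displacement window; demanding more selects against fast movers,
      # which exit the field sooner
      tracking = list(stride = 100L, link_px = 6, gap_frames = 1L, gap_px = 6,
                      min_disp_px = 5, window_s = 120, median_window = 31L,
                      min_spots = 6L)),
    snf12_wounded = list(
      kind = "vesicle", duty_cycle = 1, frac_moving = 0.4, persistent = TRUE,
      params = comet_params(speed_um_s = 0.007, speed_cv = 0.004 / 0.007,
                            n_comets_per_frame = 40, lifetime_frames = 1e6,
                            psf_sigma_px = 1.2, amplitude = amp,
                            direction_mode = "toward_point",
                            target = c(70, 70)),
      geometry = movie_geometry(140, 140, 2301, px, 0.2, background = bg,
                                background_texture_amp = 5),
      noise = noise, t0_wound = 1L, spawn_radius = c(48, 60),
      tracking = list(stride = 100L, link_px = 6, gap_frames = 1L, gap_px = 6,
                      min_disp_px = 5, window_s = 420, median_window = 31L)),
    ring_eb1 = list(
      kind = "ring",
      params = ring_params(r0_um = 4, v1_um_s = 0.08, v2_um_s = 0.008,
                           t_break_s = 20, ring_width_um = 0.24,
                           amplitude = amp),
      geometry = movie_geometry(128, 128, 301, px, 1, background = bg,
                                background_texture_amp = 5),
      noise = noise, t0_wound = 1L,
      tracking = NULL)
  )
}

#' Run a named synthetic preset
#'
#' Generates the preset's noiseless movie and ground truth, applies the
#' preset noise (with a deterministically derived child seed), and stamps the
#' preset's wound frame on the movie.
#'
#' @param name preset name; see [ww_presets()].
#' @param seed integer seed; output is fully determined by (name, seed).
#' @param overrides named list of preset fields to override (e.g. a smaller
#'   `geometry` for quick runs).
#' @return `list(movie, truth, preset)`.
#' @export
generate_preset <- function(name, seed, overrides = NULL) {
  presets <- ww_presets()
  if (!name %in% names(presets))
    stop("unknown preset '", name, "'; available: ",
         paste(names(presets), collapse = ", "))
  p <- presets[[name]]
  if (!is.null(overrides)) p <- modifyList(p, overrides)
  gen <- switch(p$kind,
    comet = generate_comet_movie(p$params, p$geometry, seed),
    vesicle = generate_vesicle_movie(p$params, p$geometry, seed,
                                     duty_cycle = p$duty_cycle %||% 1,
                                     frac_moving = p$frac_moving %||% 1,
                                     persistent = isTRUE(p$persistent),
                                     spawn_annulus = p$spawn_radius),
    ring = generate_ring_movie(p$params, p$geometry, seed))
  m <- gen$movie
  noisy <- apply_noise(m, p$noise %||% noise_params(), seed + 1000003L)
  noisy$t0_wound <- p$t0_wound %||% NA_integer_
  list(movie = noisy, truth = gen$truth, preset = p, noiseless = m,
       name = name, seed = seed)
}
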