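#' Movie geometry for the synthetic generator
#'
#' @param height_px,width_px frame size in pixels.
#' @param n_frames number of frames.
#' @param pixel_size_um,frame_interval_s calibration.
#' @param background constant background offset (counts).
#' @param background_texture_amp amplitude of an optional static low-frequency
#'   background texture (Gaussian-blurred noise), so temporal-median
#'   subtraction has something non-trivial to remove.
#' @param background_texture_sigma blur sigma (px) of that texture.
#' @export
movie_geometry <- function(height_px, width_px, n_frames, pixel_size_um,
                           frame_interval_s, background = 0,
                           background_texture_amp = 0,
                           background_texture_sigma = 8) {
  stopifnot(height_px >= 8, width_px >= 8, n_frames >= 1,
            pixel_size_um > 0, frame_interval_s > 0, background >= 0)
  list(height_px = as.integer(height_px), width_px = as.integer(width_px),
       n_frames = as.integer(n_frames), pixel_size_um = pixel_size_um,
       frame_interval_s = frame_interval_s, background = background,
       background_texture_amp = background_texture_amp,
       background_texture_sigma = background_texture_sigma)
}

#' Comet population parameters
#'
#' Parameters of the moving diffraction-limited spots (EB1 comets) the
#' generator emits. Speeds are drawn per comet from a normal distribution
#' truncated at zero with mean `speed_um_s` and coefficient of variation
#' `speed_cv`; each comet then moves in a straight line at its constant speed
#' until its lifetime expires or it reaches the frame margin.
#'
#' @param speed_um_s mean true speed (um/s), > 0.
#' @param speed_cv between-comet coefficient of variation of speed, >= 0.
#' @param n_comets_per_frame expected number of comets visible per frame.
#' @param lifetime_frames mean comet lifetime in frames (> 1); geometric.
#' @param psf_sigma_px Gaussian spot sigma in pixels (default 1, so the full
#'   spot width is about 3 px, matching the detector's blob diameter).
#' @param amplitude peak spot amplitude above background (counts).
#' @param direction_mode `"ap_biased"` (along the AP/x axis, both senses),
#'   `"isotropic"`, or `"toward_point"` (straight toward `target`).
#' @param target `(y, x)` point for `direction_mode = "toward_point"`.
#' @export
comet_params <- function(speed_um_s, speed_cv = 0, n_comets_per_frame = 10,
                         lifetime_frames = 15, psf_sigma_px = 1,
                         amplitude = 50,
                         direction_mode = c("ap_biased", "isotropic", "toward_point"),
                         target = NULL) {
  direction_mode <- match.arg(direction_mode)
  stopifnot(speed_um_s > 0, speed_cv >= 0, n_comets_per_frame > 0,
            lifetime_frames > 1, psf_sigma_px > 0, amplitude > 0)
  if (direction_mode == "toward_point" && is.null(target))
    stop("direction_mode 'toward_point' needs a target point")
  list(speed_um_s = speed_um_s, speed_cv = speed_cv,
       n_comets_per_frame = n_comets_per_frame,
       lifetime_frames = lifetime_frames, psf_sigma_px = psf_sigma_px,
       amplitude = amplitude, direction_mode = direction_mode, target = target)
}

#' Contracting-ring parameters
#'
#' Ground-truth radius trajectory `r(t) = max(0, piecewise-linear)`: slope
#' `-v1_um_s` before `t_break_s`, `-v2_um_s` after. `ring_width_um` is the
#' Gaussian sigma of the ring's radial cross-section.
#'
#' @param r0_um initial radius (um).
#' @param v1_um_s,v2_um_s fast- and slow-phase closure speeds (um/s).
#' @param t_break_s phase-change time (s).
#' @param ring_width_um radial Gaussian sigma of the ring (um).
#' @param amplitude peak ring amplitude above background.
#' @export
ring_params <- function(r0_um, v1_um_s, v2_um_s, t_break_s, ring_width_um,
                        amplitude = 50) {
  stopifnot(r0_um > 0, v1_um_s > 0, v2_um_s > 0, t_break_s > 0,
            ring_width_um > 0, amplitude > 0)
  if (r0_um <= ring_width_um)
    stop("initial radius must exceed the ring width")
  list(r0_um = r0_um, v1_um_s = v1_um_s, v2_um_s = v2_um_s,
       t_break_s = t_break_s, ring_width_um = ring_width_um,
       amplitude = amplitude)
}

#' Filament-field parameters
#'
#' @param field_mode orientation law of the filaments: `"longitudinal"` (all
#'   along the AP/x axis), `"circumferential"` (all at 90 deg),
#'   `"orthoradial"` (tangent perpendicular to the radius vector from
#'   `centre`), `"radial"`, or `"uniform_random"`.
#' @param centre `(y, x)` reference point for the radial modes.
#' @param n_filaments number of segments.
#' @param filament_length_px segment length (px).
#' @param jitter_deg Gaussian angular jitter (deg) about the law.
#' @param psf_sigma_px Gaussian cross-section sigma of a filament (px).
#' @param amplitude peak filament intensity above background.
#' @export
filament_params <- function(field_mode = c("longitudinal", "circumferential",
                                           "orthoradial", "radial",
                                           "uniform_random"),
                            centre = NULL, n_filaments = 100,
                            filament_length_px = 12, jitter_deg = 0,
                            psf_sigma_px = 1, amplitude = 50) {
  field_mode <- match.arg(field_mode)
  stopifnot(n_filaments >= 1, filament_length_px > 0, jitter_deg >= 0)
  if (field_mode %in% c("orthoradial", "radial") && is.null(centre))
    stop("radial/orthoradial field modes need a centre")
  list(field_mode = field_mode, centre = centre, n_filaments = n_filaments,
       filament_length_px = filament_length_px, jitter_deg = jitter_deg,
       psf_sigma_px = psf_sigma_px, amplitude = amplitude)
}

#' Acquisition-noise parameters
#'
#' Applied in order: exponential bleaching of the signal, Poisson photon
#' noise at `photon_scale` photons per count, additive Gaussian read noise,
#' then a linear stage drift of `drift_px_per_frame` per frame. With all
#' parameters zero the output equals the input bit-exactly.
#'
#' @param photon_scale photons per intensity count (0 disables Poisson noise).
#' @param read_sigma Gaussian read noise sd (counts).
#' @param bleach_rate_per_frame exponential decay rate of intensity per frame.
#' @param drift_px_per_frame `(dy, dx)` translation per frame.
#' @export
noise_params <- function(photon_scale = 0, read_sigma = 0,
                         bleach_rate_per_frame = 0,
                         drift_px_per_frame = c(0, 0)) {
  stopifnot(photon_scale >= 0, read_sigma >= 0, bleach_rate_per_frame >= 0,
            length(drift_px_per_frame) == 2)
  list(photon_scale = photon_scale, read_sigma = read_sigma,
       bleach_rate_per_frame = bleach_rate_per_frame,
       drift_px_per_frame = as.numeric(drift_px_per_frame))
}

# Pixel-integrated Gaussian spot: adds a spot of peak amplitude `amp` and
# sigma `sigma` at continuous centre (y, x); total added mass is
# amp * 2*pi*sigma^2 when the spot is fully inside the frame.
add_gaussian_spot <- function(img, y, x, amp, sigma) {
  H <- nrow(img); W <- ncol(img)
  R <- ceiling(4 * sigma) + 1L
  i0 <- max(1L, floor(y - R)); i1 <- min(H, ceiling(y + R))
  j0 <- max(1L, floor(x - R)); j1 <- min(W, ceiling(x + R))
  if (i0 > i1 || j0 > j1) return(img)
  ii <- i0:i1; jj <- j0:j1
  fy <- pnorm((ii + 0.5 - y) / sigma) - pnorm((ii - 0.5 - y) / sigma)
  fx <- pnorm((jj + 0.5 - x) / sigma) - pnorm((jj - 0.5 - x) / sigma)
  img[ii, jj] <- img[ii, jj] + (amp * 2 * pi * sigma^2) * outer(fy, fx)
  img
}

# Analytic anti-aliased line segment: Gaussian cross-section of sigma,
# peak amplitude `amp`; along-axis ends roll off as the Gaussian-smoothed
# indicator, so total mass = amp * sigma * sqrt(2*pi) * length for segments
# much longer than sigma.
add_gaussian_segment <- function(img, y0, x0, y1, x1, amp, sigma) {
  H <- nrow(img); W <- ncol(img)
  R <- ceiling(4 * sigma)
  i0 <- max(1L, floor(min(y0, y1) - R)); i1 <- min(H, ceiling(max(y0, y1) + R))
  j0 <- max(1L, floor(min(x0, x1) - R)); j1 <- min(W, ceiling(max(x0, x1) + R))
  if (i0 > i1 || j0 > j1) return(img)
  L <- sqrt((y1 - y0)^2 + (x1 - x0)^2)
  if (L == 0) return(add_gaussian_spot(img, y0, x0, amp, sigma))
  uy <- (y1 - y0) / L; ux <- (x1 - x0) / L
  yy <- matrix(i0:i1, i1 - i0 + 1L, j1 - j0 + 1L)
  xx <- matrix(j0:j1, i1 - i0 + 1L, j1 - j0 + 1L, byrow = TRUE)
  dy <- yy - y0; dx <- xx - x0
  s <- dy * uy + dx * ux                      # along-axis coordinate
  dperp <- dy * ux - dx * uy                  # perpendicular distance
  v <- amp * exp(-dperp^2 / (2 * sigma^2)) *
    (pnorm((L - s) / sigma) - pnorm(-s / sigma))
  img[i0:i1, j0:j1] <- img[i0:i1, j0:j1] + v
  img
}

render_background <- function(geom) {
  bg <- matrix(geom$background, geom$height_px, geom$width_px)
  if (geom$background_texture_amp > 0) {
    tex <- matrix(rnorm(geom$height_px * geom$width_px),
                  geom$height_px, geom$width_px)
    tex <- as.matrix(EBImage::gblur(tex, sigma = geom$background_texture_sigma,
                                    boundary = "replicate"))
    tex <- tex / max(sd(tex), 1e-12) * geom$background_texture_amp
    bg <- pmax(bg + tex, 0)
  }
  bg
}

# Per-object speeds: gamma with exact mean `mean_speed` and coefficient of
# variation `cv` — strictly positive, and unlike a zero-truncated normal the
# population mean equals the preset speed at any cv.
draw_speed <- function(n, mean_speed, cv) {
  if (cv == 0) return(rep(mean_speed, n))
  stats::rgamma(n, shape = 1 / cv^2, scale = mean_speed * cv^2)
}

draw_direction <- function(mode, start, target) {
  if (mode == "isotropic") {
    a <- runif(1, 0, 2 * pi)
  } else if (mode == "ap_biased") {
    a <- rnorm(1, 0, 15 * pi / 180) + sample(c(0, pi), 1)
  } else {
    a <- atan2(target[1] - start[1], target[2] - start[2])
  }
  c(sin(a), cos(a))  # (dy, dx) unit vector
}

# Simulate straight-line (optionally run-and-pause) moving spots and render
# them. Internal engine behind generate_comet_movie / generate_vesicle_movie.
simulate_spot_movie <- function(params, geom, seed, duty_cycle = 1,
                                frac_moving = 1, run_mean_frames = 10,
                                persistent = FALSE, spawn_annulus = NULL) {
  set.seed(seed)
  H <- geom$height_px; W <- geom$width_px; T <- geom$n_frames
  px <- geom$pixel_size_um; dt <- geom$frame_interval_s
  v_px <- params$speed_um_s * dt / px
  if (v_px > min(H, W))
    stop("per-frame displacement exceeds the frame size; lower the speed or ",
         "frame interval")
  margin <- max(2, 3 * params$psf_sigma_px)
  birth_rate <- params$n_comets_per_frame / params$lifetime_frames
  n0 <- rpois(1, params$n_comets_per_frame)
  births <- c(rep(1L, n0), rep(seq_len(T)[-1], rpois(T - 1, birth_rate)))
  if (persistent) births <- rep(1L, max(1L, round(params$n_comets_per_frame)))
  n_obj <- length(births)
  obj <- data.frame(object_id = seq_len(n_obj), t_start = births,
                    lifetime = NA_integer_, speed_um_s = NA_real_,
                    is_mover = NA, dir_y = NA_real_, dir_x = NA_real_)
  spots <- vector("list", n_obj)
  for (k in seq_len(n_obj)) {
    if (is.null(spawn_annulus)) {
      start <- c(runif(1, margin + 1, H - margin), runif(1, margin + 1, W - margin))
    } else {
      # spawn uniformly in an annulus around the target (area-uniform radius)
      repeat {
        r0 <- sqrt(runif(1, spawn_annulus[1]^2, spawn_annulus[2]^2))
        a0 <- runif(1, 0, 2 * pi)
        start <- params$target + r0 * c(sin(a0), cos(a0))
        if (start[1] > margin && start[1] < H - margin + 1 &&
            start[2] > margin && start[2] < W - margin + 1) break
      }
    }
    life <- if (persistent) T else min(T, rgeom(1, 1 / params$lifetime_frames) + 1L)
    mover <- runif(1) < frac_moving
    sp <- if (mover) draw_speed(1, params$speed_um_s, params$speed_cv) else 0
    dir <- draw_direction(params$direction_mode, start, params$target)
    # run/pause state sequence (TRUE = advancing)
    nfr <- min(life, T - obj$t_start[k] + 1L)
    if (nfr < 1) next
    if (!mover || duty_cycle <= 0) {
      state <- rep(FALSE, nfr)
    } else if (duty_cycle >= 1) {
      state <- rep(TRUE, nfr)
    } else {
      pause_mean <- run_mean_frames * (1 - duty_cycle) / duty_cycle
      state <- logical(0)
      cur <- runif(1) < duty_cycle
      while (length(state) < nfr) {
        len <- rgeom(1, 1 / max(if (cur) run_mean_frames else pause_mean, 1)) + 1L
        state <- c(state, rep(cur, len)); cur <- !cur
      }
      state <- state[seq_len(nfr)]
    }
    step <- sp * dt / px
    adv <- cumsum(c(0, head(state, -1) * step))
    ys <- start[1] + dir[1] * adv
    xs <- start[2] + dir[2] * adv
    inb <- ys >= 1.5 & ys <= H - 0.5 & xs >= 1.5 & xs <= W - 0.5
    keep <- if (all(inb)) seq_len(nfr) else seq_len(max(0, which.min(inb) - 1))
    if (length(keep) == 0) next
    frames_k <- obj$t_start[k] + keep - 1L
    obj$lifetime[k] <- length(keep)
    obj$speed_um_s[k] <- sp
    obj$is_mover[k] <- mover
    obj$dir_y[k] <- dir[1]; obj$dir_x[k] <- dir[2]
    spots[[k]] <- data.frame(object_id = k, frame = frames_k,
                             y_px = ys[keep], x_px = xs[keep],
                             moving = state[keep] & mover)
  }
  spots <- do.call(rbind, spots)
  obj <- obj[!is.na(obj$lifetime), , drop = FALSE]
  bg <- render_background(geom)
  arr <- array(0, dim = c(H, W, T))
  for (t in seq_len(T)) arr[, , t] <- bg
  if (!is.null(spots)) {
    for (r in seq_len(nrow(spots))) {
      t <- spots$frame[r]
      arr[, , t] <- add_gaussian_spot(arr[, , t], spots$y_px[r], spots$x_px[r],
                                      params$amplitude, params$psf_sigma_px)
    }
  }
  m <- movie(arr, px, dt)
  truth <- list(spots = spots, objects = obj, params = params, geometry = geom,
                seed = seed,
                analytic_spot_mass = params$amplitude * 2 * pi * params$psf_sigma_px^2)
  list(movie = m, truth = truth)
}

#' Generate a synthetic comet movie with ground truth
#'
#' Comets nucleate at random times and positions, move in straight lines at a
#' per-comet constant speed, disappear after a geometric lifetime (or on
#' reaching the frame margin) and are rendered as pixel-integrated Gaussian
#' spots on the background. The emitted ground truth holds every comet's
#' per-frame true position.
#'
#' @param params a [comet_params()].
#' @param geom a [movie_geometry()].
#' @param seed integer seed; (params, seed) fully determine the output.
#' @return `list(movie, truth)`; `truth$spots` is a per-frame table
#'   `object_id, frame, y_px, x_px`, `truth$objects` the per-object
#'   parameters.
#' @export
generate_comet_movie <- function(params, geom, seed) {
  simulate_spot_movie(params, geom, seed)
}

#' Generate a synthetic vesicle/cluster movie (run-and-pause motion)
#'
#' Same contract as [generate_comet_movie()], but objects alternate runs and
#' pauses with the given duty cycle (fraction of time moving), and an
#' optional static subpopulation (`frac_moving < 1`) emulates the mostly
#' static SNF-12 clusters with a moving minority. With `duty_cycle = 1` and
#' `frac_moving = 1` the statistics contract is identical to the comet
#' generator.
#'
#' @inheritParams generate_comet_movie
#' @param duty_cycle fraction of frames in the running state (0..1).
#' @param frac_moving fraction of objects that move at all.
#' @param run_mean_frames mean run-segment length (frames).
#' @param persistent if `TRUE`, objects live for the whole movie (clusters).
#' @export
generate_vesicle_movie <- function(params, geom, seed, duty_cycle = 1,
                                   frac_moving = 1, run_mean_frames = 10,
                                   persistent = FALSE, spawn_annulus = NULL) {
  simulate_spot_movie(params, geom, seed, duty_cycle = duty_cycle,
                      frac_moving = frac_moving,
                      run_mean_frames = run_mean_frames,
                      persistent = persistent, spawn_annulus = spawn_annulus)
}

#' Generate a synthetic contracting-ring movie with ground truth
#'
#' Renders an annulus centred on the wound point whose radius follows the
#' two-phase piecewise-linear trajectory of [ring_params()], with a Gaussian
#' radial cross-section.
#'
#' @param params a [ring_params()].
#' @inheritParams generate_comet_movie
#' @param centre `(y, x)` ring centre; defaults to the frame centre.
#' @return `list(movie, truth)`; `truth$radius_um` / `truth$radius_px` store
#'   r(t), `truth$centre` the programmed centre.
#' @export
generate_ring_movie <- function(params, geom, seed, centre = NULL) {
  set.seed(seed)
  H <- geom$height_px; W <- geom$width_px; T <- geom$n_frames
  px <- geom$pixel_size_um; dt <- geom$frame_interval_s
  if (is.null(centre)) centre <- c((H + 1) / 2, (W + 1) / 2)
  if (params$r0_um / px > min(H, W) / 2)
    stop("initial ring radius does not fit in the frame")
  tt <- (seq_len(T) - 1) * dt
  r_um <- ifelse(tt < params$t_break_s,
                 params$r0_um - params$v1_um_s * tt,
                 params$r0_um - params$v1_um_s * params$t_break_s -
                   params$v2_um_s * (tt - params$t_break_s))
  r_um <- pmax(r_um, 0)
  sig <- params$ring_width_um / px
  D <- sqrt(outer((seq_len(H) - centre[1])^2, (seq_len(W) - centre[2])^2, `+`))
  bg <- render_background(geom)
  arr <- array(0, dim = c(H, W, T))
  for (t in seq_len(T)) {
    rt <- r_um[t] / px
    arr[, , t] <- bg + params$amplitude * exp(-(D - rt)^2 / (2 * sig^2))
  }
  m <- movie(arr, px, dt, t0_wound = 1L)
  truth <- list(radius_um = r_um, radius_px = r_um / px, times_s = tt,
                centre = centre, params = params, geometry = geom, seed = seed)
  list(movie = m, truth = truth)
}

#' Generate a synthetic filament-texture image with ground truth
#'
#' Renders straight anti-aliased segments (Gaussian cross-section) whose
#' tangent at the midpoint follows the requested orientation law. Ground
#' truth stores each filament's true angle and, for the deterministic field
#' modes, the analytic per-pixel orientation map.
#'
#' @param params a [filament_params()].
#' @inheritParams generate_comet_movie
#' @return `list(image, truth)`.
#' @export
generate_filament_image <- function(params, geom, seed) {
  set.seed(seed)
  H <- geom$height_px; W <- geom$width_px
  L <- params$filament_length_px; sig <- params$psf_sigma_px
  margin <- 2
  img <- render_background(geom)
  fil <- data.frame(filament_id = seq_len(params$n_filaments),
                    y_px = runif(params$n_filaments, margin + 1, H - margin),
                    x_px = runif(params$n_filaments, margin + 1, W - margin),
                    angle_deg = NA_real_)
  for (k in seq_len(params$n_filaments)) {
    mid <- c(fil$y_px[k], fil$x_px[k])
    base <- switch(params$field_mode,
      longitudinal = 0,
      circumferential = 90,
      uniform_random = runif(1, 0, 180),
      radial = (atan2(params$centre[1] - mid[1],
                      params$centre[2] - mid[2]) * 180 / pi) %% 180,
      orthoradial = (atan2(params$centre[1] - mid[1],
                           params$centre[2] - mid[2]) * 180 / pi + 90) %% 180)
    a <- (base + if (params$jitter_deg > 0) rnorm(1, 0, params$jitter_deg) else 0) %% 180
    fil$angle_deg[k] <- a
    ar <- a * pi / 180
    dirv <- c(sin(ar), cos(ar))
    img <- add_gaussian_segment(img,
                                mid[1] - dirv[1] * L / 2, mid[2] - dirv[2] * L / 2,
                                mid[1] + dirv[1] * L / 2, mid[2] + dirv[2] * L / 2,
                                params$amplitude, sig)
  }
  orient_map <- NULL
  if (params$field_mode %in% c("longitudinal", "circumferential", "radial",
                               "orthoradial")) {
    orient_map <- matrix(NA_real_, H, W)
    if (params$field_mode == "longitudinal") orient_map[] <- 0
    if (params$field_mode == "circumferential") orient_map[] <- 90
    if (params$field_mode %in% c("radial", "orthoradial")) {
      beta <- atan2(params$centre[1] - row(orient_map),
                    params$centre[2] - col(orient_map)) * 180 / pi
      orient_map <- if (params$field_mode == "radial") beta %% 180
                    else (beta + 90) %% 180
    }
  }
  truth <- list(filaments = fil, orientation_map = orient_map, params = params,
                geometry = geom, seed = seed,
                analytic_line_mass = params$amplitude * sig * sqrt(2 * pi) * L)
  list(image = img, truth = truth)
}

#' Apply acquisition noise to a noiseless movie
#'
#' `out = Poisson(photon_scale * bleach(t) * in) / photon_scale +
#' N(0, read_sigma)`, then a per-frame translation of
#' `drift_px_per_frame * (t - 1)`, clipped at zero. All-zero parameters give
#' the identity bit-exactly.
#'
#' @param m a [movie()].
#' @param params a [noise_params()].
#' @param seed integer seed.
#' @export
apply_noise <- function(m, params, seed) {
  stopifnot(inherits(m, "ww_movie"))
  set.seed(seed)
  fr <- m$frames
  T <- dim(fr)[3]
  for (t in seq_len(T)) {
    f <- fr[, , t]
    if (params$bleach_rate_per_frame > 0)
      f <- f * exp(-params$bleach_rate_per_frame * (t - 1))
    if (params$photon_scale > 0)
      f <- matrix(rpois(length(f), params$photon_scale * f) / params$photon_scale,
                  nrow(f), ncol(f))
    if (params$read_sigma > 0)
      f <- f + rnorm(length(f), 0, params$read_sigma)
    dr <- params$drift_px_per_frame * (t - 1)
    if (any(dr != 0))
      f <- shift_image(f, dr[1], dr[2], fill = median(f))
    if (params$photon_scale > 0 || params$read_sigma > 0 || any(dr != 0))
      f <- pmax(f, 0)
    fr[, , t] <- f
  }
  movie(fr, m$pixel_size_um, m$frame_interval_s, m$t0_wound)
}
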