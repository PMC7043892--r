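#' Thresholded integrated-intensity recruitment trace
#'
#' Quantifies recruitment at the wound as the RawIntDen (sum of pixel
#' intensities) of the supra-threshold pixels in a wound-centred ROI
#' (protocol default: a 256 um^2 square), where the threshold is
#' `mean + k_sd * SD` of the ROI pixels pooled over the pre-wound frames.
#' Only strictly supra-threshold pixels contribute, so a movie with no
#' post-wound signal change yields a near-zero trace, and adding a constant
#' offset to the whole movie leaves the trace unchanged.
#'
#' @param m a [movie()] with `t0_wound` set (or `prewound_frames` given).
#' @param roi a [roi_spec()]; default a 256 um^2 square at the wound centre
#'   requires `centre`.
#' @param centre `(y, x)` wound centre, used when `roi` is NULL.
#' @param k_sd threshold factor (default 3).
#' @param prewound_frames frame indices to pool for the baseline; default
#'   all frames before `t0_wound`.
#' @return data frame `frame, t_s, value`; attributes `threshold`,
#'   `mode = "thresholded_rawintden"`, `sd_zero` (flag: constant baseline).
#' @export
thresholded_recruitment <- function(m, roi = NULL, centre = NULL, k_sd = 3,
                                    prewound_frames = NULL) {
  stopifnot(inherits(m, "ww_movie"))
  if (is.null(roi)) {
    if (is.null(centre)) stop("supply `roi` or `centre`")
    roi <- roi_from_area("rectangle", 256, centre, m$pixel_size_um)
  }
  if (is.null(prewound_frames)) {
    if (is.na(m$t0_wound) || m$t0_wound < 2)
      stop("no pre-wound frames: set t0_wound >= 2 or pass prewound_frames")
    prewound_frames <- seq_len(m$t0_wound - 1L)
  }
  if (length(prewound_frames) == 0) stop("empty pre-wound range")
  if (!is.na(m$t0_wound) && any(prewound_frames >= m$t0_wound))
    stop("pre-wound frames must precede t0_wound")
  mask <- roi_mask(roi, dim(m$frames))
  base <- as.vector(apply(m$frames[, , prewound_frames, drop = FALSE], 3,
                          function(f) f[mask]))
  mu <- mean(base); s <- sd(base)
  sd_zero <- !is.finite(s) || s == 0
  thr <- mu + if (sd_zero) 0 else k_sd * s
  T <- n_frames(m)
  vals <- numeric(T)
  for (t in seq_len(T)) {
    v <- m$frames[, , t][mask]
    vals[t] <- sum(v[v > thr])
  }
  out <- data.frame(frame = seq_len(T), t_s = frame_times(m), value = vals)
  attr(out, "threshold") <- thr
  attr(out, "mode") <- "thresholded_rawintden"
  attr(out, "sd_zero") <- sd_zero
  out
}

#' Mean-intensity recruitment trace
#'
#' Per-frame mean intensity of a wound-centred ROI (protocol default: an
#' 18 um^2 disc) — the statistic used for SNF-12 recruitment and for
#' calcium-burst style traces.
#'
#' @inheritParams thresholded_recruitment
#' @export
mean_intensity_trace <- function(m, roi = NULL, centre = NULL) {
  stopifnot(inherits(m, "ww_movie"))
  if (is.null(roi)) {
    if (is.null(centre)) stop("supply `roi` or `centre`")
    roi <- roi_from_area("circle", 18, centre, m$pixel_size_um)
  }
  mask <- roi_mask(roi, dim(m$frames))
  T <- n_frames(m)
  vals <- vapply(seq_len(T), function(t) mean(m$frames[, , t][mask]),
                 numeric(1))
  out <- data.frame(frame = seq_len(T), t_s = frame_times(m), value = vals)
  attr(out, "mode") <- "mean_intensity"
  out
}

#' Temporal colour-code projection
#'
#' Tints every frame with a colour from the look-up table (frame order maps
#' to hue order) and takes the per-pixel, per-channel maximum over the
#' tinted frames — the standard visualization of speed and directionality
#' over e.g. 120 frames / 2 min. A static object therefore takes, per
#' channel, the LUT colour maximizing that channel.
#'
#' @param m a [movie()].
#' @param frames frame indices to project (default all).
#' @param lut function(n) returning an n x 3 RGB matrix in [0, 1]; the
#'   default sweeps hue from red to blue.
#' @return `H x W x 3` RGB array in [0, 1] (class `ww_rgb`), writable with
#'   [png::writePNG()].
#' @export
temporal_color_projection <- function(m, frames = NULL, lut = NULL) {
  stopifnot(inherits(m, "ww_movie"))
  if (is.null(frames)) frames <- seq_len(n_frames(m))
  if (min(frames) < 1 || max(frames) > n_frames(m))
    stop("frame range outside the movie")
  if (is.null(lut))
    lut <- function(n) {
      cols <- grDevices::hsv(seq(0, 0.7, length.out = n), 1, 1)
      t(grDevices::col2rgb(cols)) / 255
    }
  colors <- lut(length(frames))
  mx <- max(m$frames[, , frames])
  if (mx == 0) mx <- 1
  d <- dim(m$frames)
  out <- array(0, dim = c(d[1], d[2], 3))
  for (i in seq_along(frames)) {
    f <- m$frames[, , frames[i]] / mx
    for (ch in 1:3) {
      cand <- f * colors[i, ch]
      out[, , ch] <- pmax(out[, , ch], cand)
    }
  }
  class(out) <- c("ww_rgb", class(out))
  out
}
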