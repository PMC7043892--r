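# Bilinear translation: out(y, x) = img(y - dy, x - dx); out-of-field = fill.
shift_image <- function(img, dy, dx, fill = 0) {
  if (dy == 0 && dx == 0) return(img)
  H <- nrow(img); W <- ncol(img)
  ys <- seq_len(H) - dy
  xs <- seq_len(W) - dx
  y0 <- floor(ys); x0 <- floor(xs)
  wy <- ys - y0; wx <- xs - x0
  gy0 <- pmin(pmax(y0, 1L), H); gy1 <- pmin(pmax(y0 + 1L, 1L), H)
  gx0 <- pmin(pmax(x0, 1L), W); gx1 <- pmin(pmax(x0 + 1L, 1L), W)
  out <- img[gy0, gx0, drop = FALSE] * outer(1 - wy, 1 - wx) +
         img[gy1, gx0, drop = FALSE] * outer(wy, 1 - wx) +
         img[gy0, gx1, drop = FALSE] * outer(1 - wy, wx) +
         img[gy1, gx1, drop = FALSE] * outer(wy, wx)
  bad_y <- ys < 1 | ys > H
  bad_x <- xs < 1 | xs > W
  out[bad_y, ] <- fill
  out[, bad_x] <- fill
  out
}

# Fourier cross-correlation with upsampled-DFT subpixel refinement; returns
# (dy, dx) such that b(y, x) ~ a(y - dy, x - dx). Mean subtraction removes
# the DC term; using the raw (not phase-normalized) cross power makes the
# subpixel peak robust to the interpolation filtering of resampled movies.
phase_corr_shift <- function(a, b, upsample = 20) {
  H <- nrow(a); W <- ncol(a)
  if (sd(a) == 0 || sd(b) == 0)
    return(list(shift = c(0, 0), degenerate = TRUE))
  FA <- fft(a - mean(a)); FB <- fft(b - mean(b))
  R <- FB * Conj(FA)
  cc <- Re(fft(R, inverse = TRUE)) / (H * W)
  pk <- arrayInd(which.max(cc), dim(cc))
  sy <- pk[1] - 1L; sx <- pk[2] - 1L
  if (sy > H / 2) sy <- sy - H
  if (sx > W / 2) sx <- sx - W
  if (upsample > 1) {
    # evaluate the cross-correlation on a fine grid around the integer peak
    ky <- c(0:(ceiling(H / 2) - 1), -(floor(H / 2):1))
    kx <- c(0:(ceiling(W / 2) - 1), -(floor(W / 2):1))
    gy <- sy + seq(-1, 1, by = 1 / upsample)
    gx <- sx + seq(-1, 1, by = 1 / upsample)
    Ey <- exp(2i * pi * outer(gy, ky) / H)      # |gy| x H
    Ex <- exp(2i * pi * outer(kx, gx) / W)      # W x |gx|
    S <- Re(Ey %*% R %*% Ex)
    pk2 <- arrayInd(which.max(S), dim(S))
    sy <- gy[pk2[1]]; sx <- gx[pk2[2]]
  }
  list(shift = c(sy, sx), degenerate = FALSE)
}

#' Estimate and correct XY stage drift by phase correlation
#'
#' Per-frame translation is estimated by phase correlation with subpixel
#' refinement (upsampled discrete Fourier transform around the integer
#' peak), then each frame is resampled by bilinear interpolation to undo the
#' estimated shift; pixels shifted in from outside the field are filled with
#' the frame median. Only pure translation is estimated.
#'
#' @param m a [movie()] with at least 2 frames.
#' @param reference `"first"` (register everything to frame 1),
#'   `"previous"` (frame-to-frame shifts, accumulated) or `"mean"`.
#' @param upsample subpixel refinement factor (shift resolution `1/upsample` px).
#' @return `list(movie, drift)`: the corrected movie and a data frame
#'   `frame, dy_px, dx_px` of estimated shifts relative to the reference
#'   frame (reference frame shift is (0, 0)); attribute `degenerate` flags
#'   all-constant frames for which a zero shift was assumed.
#' @export
register_translation <- function(m, reference = c("first", "previous", "mean"),
                                 upsample = 20) {
  stopifnot(inherits(m, "ww_movie"))
  reference <- match.arg(reference)
  T <- n_frames(m)
  if (T < 2) stop("drift correction needs at least 2 frames")
  shifts <- matrix(0, T, 2)
  degen <- logical(T)
  if (reference == "previous") {
    for (t in 2:T) {
      ps <- phase_corr_shift(m$frames[, , t - 1], m$frames[, , t], upsample)
      shifts[t, ] <- ps$shift
      degen[t] <- ps$degenerate
    }
    shifts <- apply(shifts, 2, cumsum)
  } else {
    ref <- if (reference == "first") m$frames[, , 1] else
      apply(m$frames, c(1, 2), mean)
    for (t in seq_len(T)) {
      ps <- phase_corr_shift(ref, m$frames[, , t], upsample)
      shifts[t, ] <- ps$shift
      degen[t] <- ps$degenerate
    }
    if (reference == "mean")
      shifts <- sweep(shifts, 2, shifts[1, ])
  }
  if (any(degen)) warning("constant frame(s) encountered; zero shift assumed")
  fr <- m$frames
  for (t in seq_len(T)) {
    if (any(shifts[t, ] != 0))
      fr[, , t] <- pmax(shift_image(m$frames[, , t], -shifts[t, 1],
                                    -shifts[t, 2],
                                    fill = median(m$frames[, , t])), 0)
  }
  drift <- data.frame(frame = seq_len(T), dy_px = shifts[, 1],
                      dx_px = shifts[, 2])
  attr(drift, "degenerate") <- degen
  list(movie = movie(fr, m$pixel_size_um, m$frame_interval_s, m$t0_wound),
       drift = drift)
}

#' Temporal-median background subtraction
#'
#' For every pixel, the running median of its intensity time series over a
#' centred window of `window_frames` frames is taken as the stable
#' background and subtracted frame by frame. At the movie ends the window
#' shrinks symmetrically (odd widths 1, 3, 5, ...), so early wound frames
#' remain usable. Negative residuals are clamped to zero by default.
#'
#' @param m a [movie()].
#' @param window_frames odd window length, >= 3 and <= number of frames.
#' @param clamp_negative clamp negative residuals to 0.
#' @return The background-subtracted [movie()].
#' @export
temporal_median_subtract <- function(m, window_frames = 31L,
                                     clamp_negative = TRUE) {
  stopifnot(inherits(m, "ww_movie"))
  T <- n_frames(m)
  window_frames <- as.integer(window_frames)
  if (window_frames < 3L || window_frames %% 2L == 0L)
    stop("`window_frames` must be an odd integer >= 3")
  if (window_frames > T)
    stop("`window_frames` exceeds the number of frames")
  d <- dim(m$frames)
  P <- d[1] * d[2]
  X <- t(matrix(m$frames, P, T))               # T x P, columns contiguous
  med <- X
  for (p in seq_len(P)) {
    med[, p] <- stats::runmed(X[, p], window_frames, endrule = "keep")
  }
  # shrinking symmetric (odd) windows at the stack edges, vectorized per
  # time point: sort each pixel's window and take the middle order statistic
  h <- (window_frames - 1L) %/% 2L
  edge <- which(pmin(seq_len(T) - 1L, T - seq_len(T)) < h)
  for (t in edge) {
    hh <- min(t - 1L, T - t)
    if (hh == 0L) { med[t, ] <- X[t, ]; next }
    A <- t(X[(t - hh):(t + hh), , drop = FALSE])     # P x w
    w <- 2L * hh + 1L
    srt <- matrix(A[order(row(A), A)], ncol = w, byrow = TRUE)
    med[t, ] <- srt[, hh + 1L]
  }
  out <- array(t(X - med), dim = d)
  if (clamp_negative) return(movie(pmax(out, 0), m$pixel_size_um,
                                   m$frame_interval_s, m$t0_wound))
  # unclamped residuals are legitimately negative; bypass the >= 0 invariant
  res <- movie(pmax(out, 0), m$pixel_size_um, m$frame_interval_s, m$t0_wound)
  res$frames <- out
  res
}

#' Crop a movie and/or extract a temporal substack
#'
#' Exact sub-array copy. Spatial crop uses a rectangular ROI; temporal
#' selection takes a frame range and a stride; the frame interval is
#' multiplied by the stride (e.g. stride 100 on a 0.2 s movie gives the 20 s
#' substack convention used for slow-cluster tracking).
#'
#' @param m a [movie()].
#' @param roi optional rectangular [roi_spec()].
#' @param frame_range optional `c(first, last)` frame indices.
#' @param frame_stride keep every `frame_stride`-th frame.
#' @export
crop_substack <- function(m, roi = NULL, frame_range = NULL, frame_stride = 1L) {
  stopifnot(inherits(m, "ww_movie"))
  T <- n_frames(m)
  fr <- if (is.null(frame_range)) c(1L, T) else as.integer(frame_range)
  if (fr[1] < 1 || fr[2] > T || fr[1] > fr[2]) stop("empty or out-of-bounds frame range")
  tsel <- seq(fr[1], fr[2], by = as.integer(frame_stride))
  if (length(tsel) == 0) stop("empty frame selection")
  if (!is.null(roi)) {
    if (roi$shape != "rectangle") stop("crop ROI must be rectangular")
    rows <- rect_rows(roi); cols <- rect_cols(roi)
    d <- dim(m$frames)
    if (min(rows) < 1 || max(rows) > d[1] || min(cols) < 1 || max(cols) > d[2])
      stop("crop ROI extends outside the frame")
  } else {
    rows <- seq_len(dim(m$frames)[1]); cols <- seq_len(dim(m$frames)[2])
  }
  arr <- m$frames[rows, cols, tsel, drop = FALSE]
  t0 <- m$t0_wound
  if (!is.na(t0)) {
    t0 <- which(tsel >= t0)[1]
    if (is.na(t0)) t0 <- NA_integer_
  }
  movie(arr, m$pixel_size_um, m$frame_interval_s * frame_stride, t0)
}
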