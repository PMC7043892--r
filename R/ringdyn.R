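# Otsu threshold on a 256-bin histogram (maximizing between-class variance).
otsu_threshold <- function(v) {
  lo <- min(v); hi <- max(v)
  if (hi <= lo) return(lo)
  h <- as.numeric(tabulate(pmin(floor((v - lo) / (hi - lo) * 256) + 1L, 256L),
                           256L))
  w <- cumsum(h); mu <- cumsum(h * seq_len(256))
  n <- w[256]; mtot <- mu[256]
  w1 <- w[-256]; m1 <- mu[-256]
  between <- (mtot * w1 - m1 * n)^2 / (w1 * (n - w1))
  between[!is.finite(between)] <- -Inf
  k <- which.max(between)
  lo + k / 256 * (hi - lo)
}

#' Automated wound centroid
#'
#' Intensity-weighted centroid of the pixels above the Otsu threshold within
#' the given ROI (the original protocol selected the wound area manually;
#' this automates it). Falls back to the ROI centre when the threshold
#' selects fewer than 5 pixels.
#'
#' @param img 2-D intensity matrix.
#' @param roi a [roi_spec()] containing the wound signal.
#' @return `(y, x)` centroid; attribute `fallback` is `TRUE` when the ROI
#'   centre was used.
#' @export
wound_centroid <- function(img, roi) {
  mask <- roi_mask(roi, dim(img))
  vals <- img[mask]
  thr <- otsu_threshold(vals)
  sel <- mask & img > thr
  if (sum(sel) < 5) {
    out <- roi$centre
    attr(out, "fallback") <- TRUE
    return(out)
  }
  w <- img[sel]
  idx <- which(sel, arr.ind = TRUE)
  out <- c(sum(idx[, 1] * w), sum(idx[, 2] * w)) / sum(w)
  attr(out, "fallback") <- FALSE
  out
}

#' Radial intensity profile around a centre
#'
#' Mean intensity in contiguous annular bins of `bin_width_px` starting at
#' radius 0; every in-bounds pixel contributes to exactly one bin, so
#' `sum(mean * count)` equals the total image intensity. `r_max` is the bin
#' centre of the maximum mean intensity; ties take the smallest radius and
#' are flagged as a plateau.
#'
#' The argmax is taken over complete annuli only (bins lying entirely
#' within the frame): incomplete edge/corner annuli contain few pixels and
#' their noisy means would otherwise produce spurious maxima.
#'
#' @param img 2-D intensity matrix.
#' @param centre `(y, x)` in pixels.
#' @param bin_width_px radial bin width (px).
#' @return `list(r_px, mean_intensity, count, r_max_px, plateau)`; the full
#'   profile covers every in-bounds pixel, `r_max_px` only complete annuli.
#' @export
radial_profile <- function(img, centre, bin_width_px = 1) {
  H <- nrow(img); W <- ncol(img)
  stopifnot(centre[1] >= 1, centre[1] <= H, centre[2] >= 1, centre[2] <= W)
  r <- sqrt(outer((seq_len(H) - centre[1])^2, (seq_len(W) - centre[2])^2, `+`))
  bin <- floor(r / bin_width_px) + 1L
  nb <- max(bin)
  tot <- rowsum(as.vector(img), as.vector(bin))
  cnt <- tabulate(as.vector(bin), nbins = nb)
  mu <- as.vector(tot) / cnt
  r_centres <- (seq_len(nb) - 0.5) * bin_width_px
  r_inscribed <- min(centre[1] - 1, centre[2] - 1, H - centre[1], W - centre[2])
  full <- which(r_centres <= max(r_inscribed, bin_width_px))
  imax <- full[which.max(mu[full])]
  plateau <- sum(mu[full] == mu[imax]) > 1
  list(r_px = r_centres, mean_intensity = mu, count = cnt,
       r_max_px = r_centres[imax], plateau = plateau)
}

#' Max-intensity radius versus time
#'
#' Per frame: wound centroid (automated, or a fixed supplied centre) and the
#' radius of maximum radial-profile intensity — the ring-closure trace that
#' feeds [two_phase_fit()].
#'
#' @param m a [movie()].
#' @param roi ROI for the automated centroid (defaults to the central half
#'   of the frame).
#' @param centre optional fixed `(y, x)` centre (skips centroid detection).
#' @param bin_width_px radial bin width.
#' @return data frame `frame, t_s, cy_px, cx_px, r_max_px, r_max_um`.
#' @export
ring_radius_trace <- function(m, roi = NULL, centre = NULL, bin_width_px = 1) {
  stopifnot(inherits(m, "ww_movie"))
  d <- dim(m$frames)
  if (is.null(roi) && is.null(centre))
    roi <- roi_spec("rectangle", centre = c((d[1] + 1) / 2, (d[2] + 1) / 2),
                    height_px = floor(d[1] / 2) * 2 - 2,
                    width_px = floor(d[2] / 2) * 2 - 2)
  T <- n_frames(m)
  out <- data.frame(frame = seq_len(T), t_s = frame_times(m),
                    cy_px = NA_real_, cx_px = NA_real_,
                    r_max_px = NA_real_, r_max_um = NA_real_)
  for (t in seq_len(T)) {
    ctr <- if (!is.null(centre)) centre else wound_centroid(m$frames[, , t], roi)
    rp <- radial_profile(m$frames[, , t], ctr, bin_width_px)
    out$cy_px[t] <- ctr[1]; out$cx_px[t] <- ctr[2]
    out$r_max_px[t] <- rp$r_max_px
    out$r_max_um[t] <- rp$r_max_px * m$pixel_size_um
  }
  out
}

#' Wound-centred AP kymograph
#'
#' Per frame, the signal is averaged over the circumferential (y) extent of
#' an AP-oriented stripe through the wound centre, giving a one-dimensional
#' AP profile; each profile is normalized by its maximum (all-zero rows stay
#' zero) and the rows are concatenated chronologically.
#'
#' @param m a [movie()].
#' @param centre `(y, x)` wound centre.
#' @param half_height_px stripe half-height (px).
#' @param normalize per-row max normalization (default TRUE).
#' @return An object of class `ww_kymograph`: list with `values`
#'   (frames x AP-position matrix), `x_px`, `x_um` (AP position relative to
#'   the wound centre), `t_s`, `centre`.
#' @export
build_kymograph <- function(m, centre, half_height_px = 10, normalize = TRUE) {
  stopifnot(inherits(m, "ww_movie"))
  d <- dim(m$frames)
  rows <- (round(centre[1]) - half_height_px):(round(centre[1]) + half_height_px)
  if (min(rows) < 1 || max(rows) > d[1]) stop("stripe does not fit in the frame")
  T <- n_frames(m)
  K <- matrix(0, T, d[2])
  for (t in seq_len(T)) {
    prof <- colMeans(m$frames[rows, , t, drop = FALSE][, , 1])
    if (normalize) {
      mx <- max(prof)
      prof <- if (mx > 0) prof / mx else prof * 0
    }
    K[t, ] <- prof
  }
  structure(list(values = K, x_px = seq_len(d[2]) - centre[2],
                 x_um = (seq_len(d[2]) - centre[2]) * m$pixel_size_um,
                 t_s = frame_times(m), centre = centre),
            class = "ww_kymograph")
}

#' @export
print.ww_kymograph <- function(x, ...) {
  cat(sprintf("<ww_kymograph> %d frames x %d AP positions, centre x = %g px\n",
              nrow(x$values), ncol(x$values), x$centre[2]))
  invisible(x)
}

#' Two-phase (fast/slow) closure fit
#'
#' Continuous piecewise-linear least squares with one change point:
#' `r(t) = a + b1 * min(t - t_break, 0) + b2 * max(t - t_break, 0)`.
#' The breakpoint is chosen by exhaustive search over the sample times
#' (excluding the first and last two), minimizing the residual sum of
#' squares; closure speeds are reported as absolute slopes. The fitted SSE
#' never exceeds that of a single straight line.
#'
#' @param t_s sample times (s), at least 6.
#' @param r_um radius samples (um).
#' @return An object of class `ww_phase_fit`: `v1_um_s`, `v2_um_s` (absolute
#'   slopes before/after the break), `t_break_s`, `sse`, `r2_phase1`,
#'   `r2_phase2`, `coefficients`, and the input trace.
#' @export
two_phase_fit <- function(t_s, r_um) {
  stopifnot(length(t_s) == length(r_um))
  ok <- is.finite(t_s) & is.finite(r_um)
  t_s <- t_s[ok]; r_um <- r_um[ok]
  n <- length(t_s)
  if (n < 6) stop("two-phase fit needs at least 6 samples")
  o <- order(t_s); t_s <- t_s[o]; r_um <- r_um[o]
  cands <- t_s[3:(n - 2)]
  best <- NULL
  for (tb in unique(cands)) {
    X <- cbind(1, pmin(t_s - tb, 0), pmax(t_s - tb, 0))
    fit <- lm.fit(X, r_um)
    sse <- sum(fit$residuals^2)
    if (is.null(best) || sse < best$sse - 1e-15)
      best <- list(tb = tb, sse = sse, coef = fit$coefficients,
                   fitted = fit$fitted.values)
  }
  seg1 <- t_s <= best$tb; seg2 <- t_s >= best$tb
  r2seg <- function(sel) {
    sst <- sum((r_um[sel] - mean(r_um[sel]))^2)
    if (sst == 0) return(1)
    1 - sum((r_um[sel] - best$fitted[sel])^2) / sst
  }
  structure(list(v1_um_s = unname(abs(best$coef[2])),
                 v2_um_s = unname(abs(best$coef[3])),
                 t_break_s = best$tb, sse = best$sse,
                 r2_phase1 = r2seg(seg1), r2_phase2 = r2seg(seg2),
                 coefficients = best$coef,
                 slope1 = unname(best$coef[2]), slope2 = unname(best$coef[3]),
                 t_s = t_s, r_um = r_um, fitted = best$fitted),
            class = "ww_phase_fit")
}

#' @export
print.ww_phase_fit <- function(x, ...) {
  cat("<ww_phase_fit> two-phase closure fit\n")
  cat(sprintf("  P1 (fast) speed : %.5g um/s\n", x$v1_um_s))
  cat(sprintf("  P2 (slow) speed : %.5g um/s\n", x$v2_um_s))
  cat(sprintf("  break at t = %g s; SSE = %.4g; R2 = %.3f / %.3f\n",
              x$t_break_s, x$sse, x$r2_phase1, x$r2_phase2))
  invisible(x)
}

#' @export
coef.ww_phase_fit <- function(object, ...) {
  c(v1_um_s = unname(object$v1_um_s), v2_um_s = unname(object$v2_um_s),
    t_break_s = unname(object$t_break_s))
}

#' Huang's fuzzy-entropy automatic threshold
#'
#' Minimizes the Shannon fuzziness measure over all 255 candidate
#' boundaries of a 256-bin histogram of the min-max-scaled input, with
#' membership defined by distance to the class mean (the classic
#' fuzzy-thresholding formulation). Ties take the lowest threshold.
#'
#' @param v numeric vector (or matrix) of intensities.
#' @return Threshold on the original intensity scale, strictly above the
#'   minimum and at most the maximum; classify as below iff `value < thr`.
#' @export
huang_threshold <- function(v) {
  v <- as.numeric(v)
  lo <- min(v); hi <- max(v)
  if (!(hi > lo)) stop("degenerate (constant) input: no threshold exists")
  g <- pmin(floor((v - lo) / (hi - lo) * 256), 255)   # bins 0..255
  h <- tabulate(g + 1L, 256L)
  gl <- 0:255
  W <- cumsum(h); M <- cumsum(h * gl)
  n <- W[256]; C <- 255
  best_T <- NA_integer_; best_E <- Inf
  for (T in 0:254) {
    w0 <- W[T + 1]; w1 <- n - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- M[T + 1] / w0
    mu1 <- (M[256] - M[T + 1]) / w1
    mu_of <- ifelse(gl <= T, mu0, mu1)
    u <- 1 / (1 + abs(gl - mu_of) / C)
    s <- -u * log(u) - (1 - u) * log(1 - u)
    s[u >= 1 - 1e-12] <- 0
    E <- sum(h * s) / n
    if (E < best_E - 1e-12) { best_E <- E; best_T <- T }
  }
  lo + (best_T + 0.5) / 256 * (hi - lo)
}

#' Area inside the actin ring by Huang thresholding
#'
#' Within a square ROI centred on the wound (default 80 x 80 px, the
#' 15-min-post-wound protocol), computes the Huang threshold and takes the
#' "inside" as the connected below-threshold region containing the ROI
#' centre (the ring is bright, the wound interior dark). Returns its pixel
#' count and physical area.
#'
#' @param img 2-D intensity matrix.
#' @param centre `(y, x)` wound centre.
#' @param roi_side_px ROI side length (px).
#' @param pixel_size_um calibration (optional, for `area_um2`).
#' @return `list(area_px, area_um2, threshold, mask, roi)`; `area_px` is 0
#'   with a warning attribute if the centre pixel is not below threshold.
#' @export
ring_area <- function(img, centre, roi_side_px = 80, pixel_size_um = NULL) {
  roi <- roi_spec("rectangle", centre, height_px = roi_side_px,
                  width_px = roi_side_px)
  rows <- rect_rows(roi); cols <- rect_cols(roi)
  d <- dim(img)
  if (min(rows) < 1 || max(rows) > d[1] || min(cols) < 1 || max(cols) > d[2])
    stop("ring-area ROI extends outside the frame")
  sub <- img[rows, cols]
  thr <- huang_threshold(sub)
  below <- sub < thr
  lab <- EBImage::bwlabel(below)
  cen <- c(match(round(centre[1]), rows), match(round(centre[2]), cols))
  centre_lab <- lab[cen[1], cen[2]]
  if (centre_lab == 0) {
    mask <- below & FALSE
    area <- 0L
    warn <- "centre pixel not below threshold; no interior region found"
  } else {
    mask <- lab == centre_lab
    area <- sum(mask)
    warn <- NULL
  }
  out <- list(area_px = area,
              area_um2 = if (is.null(pixel_size_um)) NA_real_ else
                area * pixel_size_um^2,
              threshold = thr, mask = mask, roi = roi)
  if (!is.null(warn)) attr(out, "warning") <- warn
  out
}

#' Intensity profile across the wound
#'
#' AP-oriented line profile through the wound centre at the requested times,
#' averaged over a 3-px circumferential band, with the physical x-axis
#' centred on the wound.
#'
#' @param m a [movie()].
#' @param centre `(y, x)` wound centre.
#' @param times_s times (s, on the [frame_times()] scale) at which to
#'   extract profiles; each is matched to the nearest frame and must fall
#'   inside the movie.
#' @param band_px band height (default 3).
#' @return data frame `t_s, frame, x_um, intensity`.
#' @export
intensity_across_wound <- function(m, centre, times_s, band_px = 3) {
  stopifnot(inherits(m, "ww_movie"))
  tt <- frame_times(m)
  d <- dim(m$frames)
  half <- floor(band_px / 2)
  rows <- (round(centre[1]) - half):(round(centre[1]) + half)
  stopifnot(min(rows) >= 1, max(rows) <= d[1])
  out <- NULL
  for (ts in times_s) {
    if (ts < min(tt) - 1e-9 || ts > max(tt) + 1e-9)
      stop("requested time ", ts, " s outside the movie")
    f <- which.min(abs(tt - ts))
    prof <- colMeans(m$frames[rows, , f, drop = FALSE][, , 1])
    out <- rbind(out, data.frame(t_s = ts, frame = f,
                                 x_um = (seq_len(d[2]) - centre[2]) *
                                   m$pixel_size_um,
                                 intensity = prof))
  }
  out
}
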