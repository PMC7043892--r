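gauss_kernel_1d <- function(sigma) {
  r <- ceiling(3 * sigma)
  x <- -r:r
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}
dgauss_kernel_1d <- function(sigma) {
  r <- ceiling(3 * sigma)
  x <- -r:r
  g <- exp(-x^2 / (2 * sigma^2))
  -x * g / (sigma^2 * sum(g))
}

#' Local texture orientation by the intensity structure tensor
#'
#' Gaussian-derivative gradients at `sigma_grad` are combined into the
#' structure tensor (Gaussian-windowed outer products of gradients at
#' `sigma_window`). The reported orientation is the axis of least gray-level
#' change — the eigenvector of the smaller tensor eigenvalue, i.e. the
#' direction a filament runs along — as an axial angle in [0, 180) degrees
#' from the +x (AP) axis. Coherency is the normalized eigenvalue contrast
#' `(l1 - l2) / (l1 + l2)` in [0, 1] (0 where the tensor trace vanishes).
#' `eigen = "large"` instead reports the dominant-gradient axis (the
#' across-ridge direction) for parity experiments.
#'
#' @param img 2-D intensity matrix.
#' @param sigma_grad gradient (derivative) scale, px.
#' @param sigma_window tensor-averaging window scale, px (>= `sigma_grad`).
#' @param eigen `"small"` (filament axis; default) or `"large"`.
#' @return An object of class `ww_orientmap`: `angle_deg` (matrix, [0, 180)),
#'   `coherency` (matrix, [0, 1]), and the scales used.
#' @export
structure_tensor_orientation <- function(img, sigma_grad = 1, sigma_window = 4,
                                         eigen = c("small", "large")) {
  eigen <- match.arg(eigen)
  stopifnot(sigma_window >= sigma_grad)
  g <- gauss_kernel_1d(sigma_grad)
  dg <- dgauss_kernel_1d(sigma_grad)
  Kx <- outer(g, dg)    # d/dx: derivative along columns
  Ky <- outer(dg, g)    # d/dy: derivative along rows
  f2 <- function(x, k) as.matrix(EBImage::filter2(x, k, boundary = "replicate"))
  gx <- f2(img, Kx)
  gy <- f2(img, Ky)
  Wk <- outer(gauss_kernel_1d(sigma_window), gauss_kernel_1d(sigma_window))
  Jxx <- f2(gx * gx, Wk); Jyy <- f2(gy * gy, Wk); Jxy <- f2(gx * gy, Wk)
  # dominant gradient axis
  phi <- 0.5 * atan2(2 * Jxy, Jxx - Jyy) * 180 / pi
  ang <- if (eigen == "small") (phi + 90) %% 180 else phi %% 180
  tr <- Jxx + Jyy
  coh <- sqrt((Jxx - Jyy)^2 + 4 * Jxy^2) / pmax(tr, 1e-300)
  coh[tr <= 0] <- 0
  coh <- pmin(pmax(coh, 0), 1)
  structure(list(angle_deg = ang, coherency = coh,
                 sigma_grad = sigma_grad, sigma_window = sigma_window,
                 eigen = eigen),
            class = "ww_orientmap")
}

#' @export
print.ww_orientmap <- function(x, ...) {
  cat(sprintf("<ww_orientmap> %d x %d px (sigma_grad %g, sigma_window %g)\n",
              nrow(x$angle_deg), ncol(x$angle_deg), x$sigma_grad,
              x$sigma_window))
  cat(sprintf("  median coherency %.3f\n", median(x$coherency)))
  invisible(x)
}

#' Wound-referenced orientation angle theta
#'
#' Per pixel, theta is the axial difference between the local texture
#' orientation and the direction from the pixel to the wound centre, folded
#' into [0, 90]: 0 deg = radial (pointing at the wound), 90 deg =
#' orthoradial (tangential). Pixels with coherency below `coherency_min`,
#' and the centre pixel itself, are masked invalid.
#'
#' @param omap a [structure_tensor_orientation()] result.
#' @param centre `(y, x)` wound centre.
#' @param coherency_min validity cutoff on coherency.
#' @return An object of class `ww_thetamap`: `theta_deg` (matrix, [0, 90]),
#'   `valid` (logical matrix), `orient_deg`, `centre`, `coherency_min`.
#' @export
theta_map <- function(omap, centre, coherency_min = 0.2) {
  stopifnot(inherits(omap, "ww_orientmap"))
  H <- nrow(omap$angle_deg); W <- ncol(omap$angle_deg)
  stopifnot(centre[1] >= 1, centre[1] <= H, centre[2] >= 1, centre[2] <= W)
  yy <- matrix(seq_len(H), H, W)
  xx <- matrix(seq_len(W), H, W, byrow = TRUE)
  beta <- (atan2(centre[1] - yy, centre[2] - xx) * 180 / pi) %% 180
  delta <- abs(omap$angle_deg - beta) %% 180
  theta <- pmin(delta, 180 - delta)
  at_centre <- abs(yy - centre[1]) < 0.5 & abs(xx - centre[2]) < 0.5
  valid <- omap$coherency >= coherency_min & !at_centre
  theta[at_centre] <- NA_real_
  structure(list(theta_deg = theta, valid = valid,
                 orient_deg = omap$angle_deg, centre = as.numeric(centre),
                 coherency_min = coherency_min),
            class = "ww_thetamap")
}

#' @export
print.ww_thetamap <- function(x, ...) {
  cat(sprintf("<ww_thetamap> centre (%g, %g); %d valid px; mean theta %.1f deg\n",
              x$centre[1], x$centre[2], sum(x$valid),
              mean(x$theta_deg[x$valid])))
  invisible(x)
}

#' Annular sectors around the wound
#'
#' Three concentric annuli R1, R2, R3 over which theta is averaged, defined
#' by radii `0 < r0 < r1 < r2 < r3` in micrometres.
#'
#' @param centre `(y, x)` wound centre (px).
#' @param radii_um increasing radii `(r0, r1, r2, r3)` in um.
#' @param pixel_size_um calibration.
#' @export
sector_spec <- function(centre, radii_um = c(1, 4, 8, 12), pixel_size_um) {
  stopifnot(length(radii_um) == 4, all(diff(radii_um) > 0), radii_um[1] > 0,
            pixel_size_um > 0)
  list(centre = as.numeric(centre), radii_um = radii_um,
       radii_px = radii_um / pixel_size_um, pixel_size_um = pixel_size_um)
}

sector_indices <- function(tmap, sectors) {
  H <- nrow(tmap$theta_deg); W <- ncol(tmap$theta_deg)
  r <- sqrt(outer((seq_len(H) - sectors$centre[1])^2,
                  (seq_len(W) - sectors$centre[2])^2, `+`))
  lapply(1:3, function(k)
    which(tmap$valid & r >= sectors$radii_px[k] & r < sectors$radii_px[k + 1]))
}

#' Per-sector statistics of theta
#'
#' For each annulus: the arithmetic mean of valid theta (the primary
#' statistic — theta is a folded magnitude in [0, 90], not a circular
#' variable), its standard deviation, and, as a secondary statistic, the
#' axial circular mean and resultant length of the underlying orientations
#' (doubled-angle convention). Sectors with no valid pixels are flagged.
#'
#' @param tmap a [theta_map()].
#' @param sectors a [sector_spec()].
#' @return data frame with one row per sector: `sector, r_lo_um, r_hi_um, n,
#'   mean_theta_deg, sd_theta_deg, circ_mean_orient_deg, circ_R`.
#' @export
sector_stats <- function(tmap, sectors) {
  idx <- sector_indices(tmap, sectors)
  out <- data.frame(sector = c("R1", "R2", "R3"),
                    r_lo_um = sectors$radii_um[1:3],
                    r_hi_um = sectors$radii_um[2:4],
                    n = vapply(idx, length, integer(1)),
                    mean_theta_deg = NA_real_, sd_theta_deg = NA_real_,
                    circ_mean_orient_deg = NA_real_, circ_R = NA_real_)
  for (k in 1:3) {
    if (out$n[k] == 0) next
    th <- tmap$theta_deg[idx[[k]]]
    out$mean_theta_deg[k] <- mean(th)
    out$sd_theta_deg[k] <- sd(th)
    a2 <- tmap$orient_deg[idx[[k]]] * 2 * pi / 180
    z <- complex(real = mean(cos(a2)), imaginary = mean(sin(a2)))
    out$circ_mean_orient_deg[k] <- (Arg(z) * 180 / pi / 2) %% 180
    out$circ_R[k] <- Mod(z)
  }
  out
}

#' Permutation test comparing sector theta before and after wounding
#'
#' Two-sample permutation test on the per-sector mean theta (pixel labels
#' shuffled between the two maps within each sector), two-sided,
#' deterministic given the seed. The original analysis used an unspecified
#' circular-statistics test; since theta is a folded magnitude, a
#' permutation test on its mean is the assumption-free choice.
#'
#' @param tmap0,tmap1 [theta_map()]s sharing geometry (e.g. just before and
#'   10 min after wounding).
#' @param sectors a [sector_spec()].
#' @param n_permutations number of label permutations.
#' @param seed integer seed.
#' @return data frame `sector, n0, n1, mean0, mean1, p_value` (`p_value`
#'   `NA` for empty sectors).
#' @export
compare_before_after <- function(tmap0, tmap1, sectors,
                                 n_permutations = 1000, seed = 1) {
  idx0 <- sector_indices(tmap0, sectors)
  idx1 <- sector_indices(tmap1, sectors)
  set.seed(seed)
  out <- data.frame(sector = c("R1", "R2", "R3"),
                    n0 = vapply(idx0, length, integer(1)),
                    n1 = vapply(idx1, length, integer(1)),
                    mean0 = NA_real_, mean1 = NA_real_, p_value = NA_real_)
  for (k in 1:3) {
    x <- tmap0$theta_deg[idx0[[k]]]
    y <- tmap1$theta_deg[idx1[[k]]]
    if (length(x) == 0 || length(y) == 0) next
    out$mean0[k] <- mean(x); out$mean1[k] <- mean(y)
    obs <- mean(y) - mean(x)
    pool <- c(x, y)
    n1 <- length(y)
    cnt <- 0L
    for (b in seq_len(n_permutations)) {
      sel <- sample.int(length(pool), n1)
      if (abs(mean(pool[sel]) - mean(pool[-sel])) >= abs(obs) - 1e-12)
        cnt <- cnt + 1L
    }
    out$p_value[k] <- (1 + cnt) / (n_permutations + 1)
  }
  out
}
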