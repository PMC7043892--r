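test_that("wound centroid finds a symmetric ring centre within 0.5 px", {
  img <- ring_image(20, centre = c(64, 64)) + 10
  roi <- roi_spec("rectangle", c(64, 64), height_px = 80, width_px = 80)
  ctr <- wound_centroid(img, roi)
  expect_lt(abs(ctr[1] - 64), 0.5)
  expect_lt(abs(ctr[2] - 64), 0.5)
  expect_false(attr(ctr, "fallback"))
})

test_that("uniform ROI falls back to the ROI centre", {
  img <- matrix(50, 64, 64)
  roi <- roi_spec("rectangle", c(30, 35), height_px = 20, width_px = 20)
  ctr <- wound_centroid(img, roi)
  expect_true(attr(ctr, "fallback"))
  expect_equal(as.numeric(ctr), c(30, 35))
})

test_that("centroid RMS error on a noisy programmed ring stays below 1 px", {
  res <- generate_preset("ring_eb1", 3,
    overrides = list(geometry = movie_geometry(128, 128, 20, 0.08, 1,
                                               background = 100,
                                               background_texture_amp = 5)))
  roi <- roi_spec("rectangle", c(64.5, 64.5), height_px = 100, width_px = 100)
  errs <- vapply(1:20, function(t) {
    ctr <- wound_centroid(res$movie$frames[, , t], roi)
    sqrt(sum((ctr - res$truth$centre)^2))
  }, numeric(1))
  expect_lt(sqrt(mean(errs^2)), 1)
})

test_that("radial profile: argmax radius, tie rule, mass conservation", {
  img <- ring_image(10, centre = c(64, 64), sigma = 1.5)
  rp <- radial_profile(img, c(64, 64))
  expect_lt(abs(rp$r_max_px - 10), 1)
  # mass conservation
  expect_equal(sum(rp$mean_intensity * rp$count), sum(img),
               tolerance = 1e-6 * sum(img))
  # centred uniform disc: profile flat then drops; argmax is the first bin
  H <- 64
  D <- sqrt(outer((1:H - 32.5)^2, (1:H - 32.5)^2, `+`))
  disc <- (D <= 12) * 100
  rp2 <- radial_profile(disc, c(32.5, 32.5))
  expect_equal(rp2$r_max_px, 0.5)
  expect_true(rp2$plateau)
})

test_that("kymograph rows are max-normalized AP profiles", {
  # static bright vertical line at x = 20
  arr <- array(0, c(32, 64, 5))
  arr[, 20, ] <- 50
  m <- movie(arr, 0.1, 1)
  ky <- build_kymograph(m, centre = c(16, 32), half_height_px = 10)
  expect_equal(dim(ky$values), c(5, 64))
  expect_true(all(ky$values[, 20] == 1))
  expect_true(all(ky$values[, -20] == 0))
  # all-zero frame stays an all-zero row (0/0 -> 0)
  arr2 <- arr; arr2[, , 3] <- 0
  ky2 <- build_kymograph(movie(arr2, 0.1, 1), c(16, 32), 10)
  expect_true(all(ky2$values[3, ] == 0))
  expect_true(all(apply(ky$values, 1, max) %in% c(0, 1)))
})

test_that("kymograph edges of a contracting ring converge as 2 r(t)", {
  res <- generate_ring_movie(ring_params(4, 0.08, 0.008, 20, 0.24, 52),
                             movie_geometry(128, 128, 40, 0.08, 1,
                                            background = 0), 1)
  ky <- build_kymograph(res$movie, res$truth$centre, half_height_px = 2)
  for (t in c(5, 15, 30)) {
    row <- ky$values[t, ]
    pk_left <- which.max(row[1:64])
    pk_right <- 64 + which.max(row[65:128])
    sep <- pk_right - pk_left
    expect_lt(abs(sep - 2 * res$truth$radius_px[t]), 2)
  }
})

test_that("two-phase fit recovers a noiseless piecewise trace exactly", {
  tt <- seq(0, 300, by = 1)
  r <- ifelse(tt < 50, 4 - 0.08 * tt, 4 - 0.08 * 50 - 0.008 * (tt - 50))
  fit <- two_phase_fit(tt, r)
  expect_equal(fit$v1_um_s, 0.08, tolerance = 1e-9)
  expect_equal(fit$v2_um_s, 0.008, tolerance = 1e-9)
  expect_equal(fit$t_break_s, 50, tolerance = 1e-9)
  expect_lt(fit$sse, 1e-9)
  expect_equal(coef(fit)[["t_break_s"]], 50)
})

test_that("single-slope traces fit with v1 = v2", {
  tt <- seq(0, 100, by = 2)
  fit <- two_phase_fit(tt, 5 - 0.02 * tt)
  expect_lt(abs(fit$v1_um_s - fit$v2_um_s), 1e-6)
  expect_lt(fit$sse, 1e-12)
})

test_that("two-phase SSE never exceeds the single-line SSE", {
  set.seed(21)
  for (rep in 1:20) {
    tt <- sort(runif(25, 0, 100))
    r <- 5 - 0.03 * tt + rnorm(25, 0, 0.2)
    fit <- two_phase_fit(tt, r)
    sse1 <- sum(lm.fit(cbind(1, tt), r)$residuals^2)
    expect_lte(fit$sse, sse1 + 1e-9)
    expect_gte(fit$t_break_s, tt[3] - 1e-9)
    expect_lte(fit$t_break_s, tt[23] + 1e-9)
  }
  expect_error(two_phase_fit(1:5, 1:5), "6 samples")
})

test_that("Huang threshold equals the exhaustive fuzziness oracle exactly", {
  set.seed(22)
  for (rep in 1:50) {
    v <- sample(0:255, 400, TRUE)
    if (min(v) == max(v)) next
    expect_identical(huang_threshold(v), huang_oracle(v))
  }
})

test_that("Huang threshold respects range bounds and rejects constants", {
  set.seed(23)
  for (rep in 1:10) {
    v <- runif(200, 10, 200)
    thr <- huang_threshold(v)
    expect_gt(thr, min(v))
    expect_lte(thr, max(v))
  }
  expect_error(huang_threshold(rep(5, 10)), "constant")
})

test_that("ring area: two-level ring image recovers the interior disc", {
  H <- 100
  D <- sqrt(outer((1:H - 50.5)^2, (1:H - 50.5)^2, `+`))
  img <- matrix(50, H, H)
  img[D >= 9 & D <= 13] <- 200     # bright ring
  ra <- ring_area(img, c(50.5, 50.5), roi_side_px = 80, pixel_size_um = 0.1)
  expect_gt(ra$threshold, 50); expect_lt(ra$threshold, 200)
  interior <- sum(D < 9)
  expect_equal(ra$area_px, interior, tolerance = 1e-9)
  expect_equal(ra$area_um2, interior * 0.01, tolerance = 1e-9)
})

test_that("ring area on the noisy ring preset matches the noiseless geometry", {
  res <- generate_preset("ring_eb1", 2)
  t <- 21   # r(20 s) = 2.4 um = 30 px, well inside the 80 px ROI
  ra_noisy <- ring_area(res$movie$frames[, , t], res$truth$centre,
                        roi_side_px = 80, pixel_size_um = 0.08)
  ra_clean <- ring_area(res$noiseless$frames[, , t], res$truth$centre,
                        roi_side_px = 80, pixel_size_um = 0.08)
  # noiseless interior is the programmed disc inside the ring's inner edge
  r_px <- res$truth$radius_px[t]
  expect_lt(abs(sqrt(ra_clean$area_px / pi) - r_px) / r_px, 0.2)
  # noise changes the measured interior by less than 15%
  expect_lt(abs(ra_noisy$area_px - ra_clean$area_px) / ra_clean$area_px, 0.15)
})

test_that("ring-area trace on a closing ring is non-increasing after smoothing", {
  res <- generate_preset("ring_eb1", 4,
    overrides = list(geometry = movie_geometry(128, 128, 120, 0.08, 1,
                                               background = 100,
                                               background_texture_amp = 5)))
  frames <- seq(21, 111, by = 10)   # ring inside the 80 px ROI throughout
  areas <- vapply(frames, function(t)
    ring_area(res$movie$frames[, , t], res$truth$centre, 80)$area_px,
    numeric(1))
  sm <- stats::filter(areas, rep(1 / 3, 3))
  sm <- sm[!is.na(sm)]
  expect_true(all(diff(sm) <= 0.05 * max(areas)))
  expect_lt(tail(sm, 1), head(sm, 1))
})

test_that("intensity profiles across the wound show the expected geometry", {
  res <- generate_ring_movie(ring_params(3, 0.05, 0.005, 30, 0.24, 52),
                             movie_geometry(128, 128, 60, 0.08, 1,
                                            background = 0), 5)
  prof <- intensity_across_wound(res$movie, res$truth$centre, times_s = c(10, 40))
  for (ts in c(10, 40)) {
    pp <- prof[prof$t_s == ts, ]
    t_idx <- pp$frame[1]
    r_um <- res$truth$radius_um[t_idx]
    # two peaks at +/- r(t)
    left <- pp[pp$x_um < 0, ]; right <- pp[pp$x_um > 0, ]
    expect_lt(abs(left$x_um[which.max(left$intensity)] + r_um), 2 * 0.08)
    expect_lt(abs(right$x_um[which.max(right$intensity)] - r_um), 2 * 0.08)
    # symmetry about the wound
    mid <- pp$intensity
    expect_equal(mid, rev(mid), tolerance = 0.15 * max(mid))
  }
  # constant image: constant profile
  pc <- intensity_across_wound(const_movie(9, H = 32, W = 32, T = 4),
                               c(16, 16), times_s = 1)
  expect_true(all(pc$intensity == 9))
  expect_error(intensity_across_wound(const_movie(), c(8, 8), times_s = 1e6),
               "outside")
})
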