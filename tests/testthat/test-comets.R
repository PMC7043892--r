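test_that("spot detection: blank and constant frames yield no spots", {
  expect_identical(nrow(detect_spots(matrix(0, 64, 64))), 0L)
  expect_identical(nrow(detect_spots(matrix(100, 64, 64))), 0L)
})

test_that("a clean Gaussian spot is localized within 0.5 px", {
  img <- spot_image(30.3, 40.7, amp = 52, sigma = 1)
  sp <- detect_spots(img)
  expect_identical(nrow(sp), 1L)
  expect_lt(abs(sp$y_px - 30.3), 0.5)
  expect_lt(abs(sp$x_px - 40.7), 0.5)
})

test_that("well-separated noisy spots are all detected and matched within 1 px", {
  set.seed(3)
  img <- matrix(0, 128, 128)
  pts <- NULL
  while (is.null(pts) || nrow(pts) < 20) {
    cand <- c(runif(1, 10, 118), runif(1, 10, 118))
    if (is.null(pts) ||
        all(sqrt((pts[, 1] - cand[1])^2 + (pts[, 2] - cand[2])^2) >= 6))
      pts <- rbind(pts, cand)
  }
  for (i in 1:20) img <- wormwound:::add_gaussian_spot(img, pts[i, 1],
                                                       pts[i, 2], 52, 1)
  noisy <- matrix(rpois(128^2, img + 100) - 100, 128, 128)
  sp <- detect_spots(noisy)
  D <- sqrt(outer(pts[, 1], sp$y_px, `-`)^2 + outer(pts[, 2], sp$x_px, `-`)^2)
  expect_identical(sum(apply(D, 1, min) <= 1), 20L)
})

test_that("frame-pair linking equals brute-force minimal-cost matching", {
  set.seed(7)
  for (rep in 1:40) {
    n <- sample(0:7, 1); m <- sample(0:7, 1)
    ay <- runif(n, 0, 10); ax <- runif(n, 0, 10)
    by <- runif(m, 0, 10); bx <- runif(m, 0, 10)
    links <- wormwound:::match_points(ay, ax, by, bx, 3)
    got <- match_cost(links, ay, ax, by, bx, 3)
    want <- brute_force_match_cost(ay, ax, by, bx, 3)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("linking follows the 2 px / gap 1 protocol", {
  # 1 px steps: one track
  sp <- data.frame(frame = 1:10, y_px = 5,
                   x_px = seq(5, by = 1, length.out = 10), intensity = 1)
  expect_identical(length(unique(link_tracks(sp)$track_id)), 1L)
  # spot missing at frame 5: gap closed, still one track
  expect_identical(length(unique(link_tracks(sp[-5, ])$track_id)), 1L)
  # two missing frames: cannot be closed at gap 1
  expect_identical(length(unique(link_tracks(sp[-(5:6), ])$track_id)), 2L)
  # 3 px steps: no links at a 2 px gate
  sp3 <- data.frame(frame = 1:10, y_px = 5,
                    x_px = seq(5, by = 3, length.out = 10), intensity = 1)
  expect_identical(length(unique(link_tracks(sp3)$track_id)), 10L)
})

test_that("linking conserves spots: every detection is in exactly one track", {
  set.seed(8)
  sp <- data.frame(frame = rep(1:15, each = 6),
                   y_px = runif(90, 1, 60), x_px = runif(90, 1, 60),
                   intensity = 1)
  tr <- link_tracks(sp, link_params(4, 1, 4))
  expect_identical(nrow(tr), nrow(sp))
  expect_false(any(is.na(tr$track_id)))
  # within a track, frames strictly increase and step gates hold
  for (id in unique(tr$track_id)) {
    tt <- tr[tr$track_id == id, ]
    expect_true(all(diff(tt$frame) >= 1))
    expect_true(all(diff(tt$frame) <= 2))
    if (nrow(tt) > 1)
      expect_true(all(sqrt(diff(tt$y_px)^2 + diff(tt$x_px)^2) <= 4 + 1e-9))
  }
})

test_that("track speed arithmetic is exact on constructed tracks", {
  # constant 0.5 px steps at 0.1 um/px and 0.5 s/frame: 0.1 um/s
  tr <- data.frame(track_id = 1, frame = 1:10, y_px = 5,
                   x_px = seq(2, by = 0.5, length.out = 10))
  st <- track_stats(tr, 0.1, 0.5)
  expect_equal(st$mean_step_speed_um_s, 0.1, tolerance = 1e-12)
  expect_equal(st$net_speed_um_s, 0.1, tolerance = 1e-12)
  expect_equal(st$msd_speed_um_s, 0.1, tolerance = 1e-12)
  expect_equal(st$path_length_um, 9 * 0.05, tolerance = 1e-12)
  expect_gte(st$path_length_um, st$net_displacement_um - 1e-12)
  # static track: zero speed
  tr0 <- data.frame(track_id = 1, frame = 1:5, y_px = 3, x_px = 3)
  expect_equal(track_stats(tr0, 0.1, 0.5)$mean_step_speed_um_s, 0)
  # gap-spanning step divided by the true elapsed time
  trg <- data.frame(track_id = 1, frame = c(1, 2, 4), y_px = 0,
                    x_px = c(0, 1, 3))
  st <- track_stats(trg, 1, 1)
  expect_equal(st$mean_step_speed_um_s, 1)
  # singleton: NA speed
  expect_true(is.na(track_stats(data.frame(track_id = 1, frame = 1, y_px = 1,
                                           x_px = 1), 1, 1)$mean_step_speed_um_s))
  expect_error(track_speed(data.frame(frame = 1, y_px = 1, x_px = 1), 1, 1),
               "singleton")
})

test_that("jitter-corrected MSD speed removes localization-noise inflation", {
  set.seed(9)
  v_px <- 0.6; sigma <- 0.2
  sp <- c()
  for (rep in 1:200) {
    n <- 15
    tr <- data.frame(track_id = 1, frame = 1:n,
                     y_px = rnorm(n, 0, sigma),
                     x_px = v_px * (1:n) + rnorm(n, 0, sigma))
    sp <- c(sp, track_stats(tr, 1, 1)$msd_speed_um_s)
  }
  expect_equal(mean(sp), v_px, tolerance = 0.03)
  # whereas the naive mean step speed is visibly inflated
  naive <- c()
  set.seed(9)
  for (rep in 1:200) {
    n <- 15
    tr <- data.frame(track_id = 1, frame = 1:n,
                     y_px = rnorm(n, 0, sigma),
                     x_px = v_px * (1:n) + rnorm(n, 0, sigma))
    naive <- c(naive, track_stats(tr, 1, 1)$mean_step_speed_um_s)
  }
  expect_gt(mean(naive), v_px * 1.05)
})

test_that("minimum-displacement filter implements the 5 px / 120 s rule", {
  # 4 px over 120 s: removed
  tr4 <- data.frame(track_id = 1, frame = 1:121, y_px = 0,
                    x_px = seq(0, 4, length.out = 121))
  expect_identical(nrow(filter_min_displacement(tr4, 5, 120, 1)), 0L)
  # straight 6 px in 100 s: kept
  tr6 <- data.frame(track_id = 1, frame = 1:101, y_px = 0,
                    x_px = seq(0, 6, length.out = 101))
  expect_identical(nrow(filter_min_displacement(tr6, 5, 120, 1)), 101L)
  # oscillation of +/-1 px forever: removed
  tro <- data.frame(track_id = 1, frame = 1:300, y_px = 0,
                    x_px = rep(c(0, 1), 150))
  expect_identical(nrow(filter_min_displacement(tro, 5, 120, 1)), 0L)
  # slow drifts larger than the window displacement are removed too
  trs <- data.frame(track_id = 1, frame = 1:1000, y_px = 0,
                    x_px = seq(0, 8, length.out = 1000))  # 8 px in 1000 s
  expect_identical(nrow(filter_min_displacement(trs, 5, 120, 1)), 0L)
})

test_that("track vectors: AP and wound-referenced angle conventions", {
  trx <- data.frame(track_id = 1, frame = 1:3, y_px = 10, x_px = c(1, 2, 3))
  tv <- track_vectors(trx, "ap")
  expect_equal(tv$angles$angle_deg[1], 0)
  # toward the wound: 0 degrees
  trw <- data.frame(track_id = 1, frame = 1:3, y_px = c(10, 8, 6),
                    x_px = c(10, 8, 6))
  tvw <- track_vectors(trw, reference = c(2, 2))
  expect_equal(tvw$angles$angle_deg[1], 0, tolerance = 1e-5)
  # directly away from the wound: 180 degrees
  tva <- track_vectors(trw, reference = c(14, 14))
  expect_equal(tva$angles$angle_deg[1], 180, tolerance = 1e-5)
  # zero-displacement tracks are excluded and counted
  trz <- rbind(trw, data.frame(track_id = 2, frame = 1:2, y_px = 5, x_px = 5))
  tvz <- track_vectors(trz, reference = c(2, 2))
  expect_identical(tvz$n_excluded, 1L)
  # frequencies sum to one
  expect_equal(sum(tvz$histogram$freq), 1, tolerance = 1e-12)
})

test_that("angle histograms are translation-invariant and reflection-symmetric", {
  set.seed(11)
  tracks <- do.call(rbind, lapply(1:50, function(id) {
    a <- runif(1, 0, 2 * pi)
    data.frame(track_id = id, frame = 1:5,
               y_px = 50 + sin(a) * (0:4), x_px = 50 + cos(a) * (0:4))
  }))
  h1 <- track_vectors(tracks, "ap")$histogram
  shifted <- tracks
  shifted$y_px <- shifted$y_px + 17.3; shifted$x_px <- shifted$x_px - 4.2
  h2 <- track_vectors(shifted, "ap")$histogram
  expect_equal(h1$freq, h2$freq, tolerance = 1e-12)
  # reflection about the AP axis mirrors each axial angle to (180 - a) %% 180
  reflected <- tracks; reflected$y_px <- -reflected$y_px + 100
  a1 <- track_vectors(tracks, "ap")$angles$angle_deg
  a3 <- track_vectors(reflected, "ap")$angles$angle_deg
  expect_equal(a3, (180 - a1) %% 180, tolerance = 1e-9)
})

test_that("isotropic generator yields a uniform wound-referenced histogram", {
  set.seed(12)
  g <- movie_geometry(400, 400, 12, 0.08, 0.3)
  p <- comet_params(1, 0, 180, 12, 1, 52, "isotropic")
  res <- generate_comet_movie(p, g, 12)
  tr <- res$truth$spots
  names(tr)[names(tr) == "object_id"] <- "track_id"
  tv <- track_vectors(tr, "ap")
  n <- sum(!is.na(tv$angles$angle_deg))
  h <- tv$histogram$freq * n
  expect_gt(chisq.test(h)$p.value, 0.01)
})

test_that("spot density follows count / area", {
  dimHW <- c(100, 100)
  roi <- roi_spec("rectangle", c(50.5, 50.5), height_px = 50, width_px = 50)
  # 30 spots inside a known-area ROI
  set.seed(13)
  sp <- data.frame(frame = 1, y_px = runif(30, 30, 70), x_px = runif(30, 30, 70))
  px <- sqrt(300) / 50   # ROI area = 300 um^2
  d <- spot_density(sp, roi, dimHW, px)
  expect_equal(d$area_um2, 300, tolerance = 1e-9)
  expect_equal(d$density_per_um2, 0.1, tolerance = 1e-9)
  # empty ROI
  sp0 <- data.frame(frame = integer(0), y_px = numeric(0), x_px = numeric(0))
  expect_equal(spot_density(sp0, roi, dimHW, px)$count, 0)
})

test_that("mean spot density over frames matches Poisson expectation", {
  set.seed(14)
  lambda <- 20; A <- 300
  frames <- 50
  sp <- do.call(rbind, lapply(seq_len(frames), function(f) {
    n <- rpois(1, lambda)
    data.frame(frame = f, y_px = runif(n, 30, 70), x_px = runif(n, 30, 70))
  }))
  roi <- roi_spec("rectangle", c(50.5, 50.5), height_px = 50, width_px = 50)
  px <- sqrt(A) / 50
  d <- spot_density(sp, roi, c(100, 100), px)
  se <- sqrt(lambda / frames) / A
  expect_lt(abs(d$density_per_um2 - lambda / A), 3 * se)
})
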