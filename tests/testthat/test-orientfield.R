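test_that("structure tensor recovers the orientation of parallel lines", {
  # parallel 30-degree lines drawn directly
  img <- matrix(0, 128, 128)
  a <- 30 * pi / 180
  for (off in seq(-60, 60, by = 8)) {
    mid <- c(64 + off * cos(a), 64 - off * sin(a))
    for (s in seq(-40, 40, by = 0.25))
      img <- wormwound:::add_gaussian_spot(img, mid[1] + sin(a) * s,
                                           mid[2] + cos(a) * s, 5, 1)
  }
  omap <- structure_tensor_orientation(img)
  sel <- omap$coherency > 0.8 & img > 0.5 * max(img)
  ang <- omap$angle_deg[sel]
  dd <- abs(ang - 30) %% 180
  expect_lt(median(pmin(dd, 180 - dd)), 2)
  expect_gt(mean(omap$coherency[sel]), 0.8)
})

test_that("horizontal stripes (intensity varying only with y) orient at 0", {
  img <- matrix(sin(seq(0, 8 * pi, length.out = 96)), 96, 96)[, rep(1, 96)]
  img <- img - min(img)
  omap <- structure_tensor_orientation(img)
  core <- omap$angle_deg[20:76, 20:76]
  dd <- pmin(core %% 180, 180 - core %% 180)
  expect_lt(max(dd), 1)
})

test_that("white noise yields low coherency", {
  set.seed(31)
  img <- matrix(runif(96 * 96), 96, 96)
  omap <- structure_tensor_orientation(img)
  expect_lt(median(omap$coherency), 0.3)
})

test_that("rotating the image by 90 degrees rotates orientations by 90", {
  set.seed(32)
  res <- generate_filament_image(
    filament_params("uniform_random", n_filaments = 60,
                    filament_length_px = 14),
    movie_geometry(96, 96, 1, 0.08, 1), 32)
  img <- res$image
  rot <- t(img)[, nrow(img):1]   # 90-degree rotation
  o1 <- structure_tensor_orientation(img)
  o2 <- structure_tensor_orientation(rot)
  sel <- o1$coherency > 0.6
  sel[c(1:8, 89:96), ] <- FALSE; sel[, c(1:8, 89:96)] <- FALSE
  idx <- which(sel, arr.ind = TRUE)
  # pixel (y, x) maps to (x, H + 1 - y) under this rotation
  a1 <- o1$angle_deg[idx]
  a2 <- o2$angle_deg[cbind(idx[, 2], 96 + 1 - idx[, 1])]
  dd <- abs((a1 + 90) %% 180 - a2)
  dd <- pmin(dd, 180 - dd)
  expect_lt(median(dd), 3)
})

test_that("theta is 90 on concentric circles and 0 on radial spokes", {
  H <- 128; ctr <- c(64.5, 64.5)
  D <- sqrt(outer((1:H - ctr[1])^2, (1:H - ctr[2])^2, `+`))
  rings <- 50 + 50 * sin(D * 1.2)
  om <- structure_tensor_orientation(rings)
  tm <- theta_map(om, ctr)
  sel <- tm$valid & D > 15 & D < 55
  expect_lt(abs(mean(tm$theta_deg[sel]) - 90), 3)
  # radial spokes
  ang <- atan2(outer(1:H, rep(1, H)) - ctr[1],
               outer(rep(1, H), 1:H) - ctr[2])
  spokes <- 50 + 50 * sin(ang * 36)
  om2 <- structure_tensor_orientation(spokes)
  tm2 <- theta_map(om2, ctr)
  sel2 <- tm2$valid & D > 25 & D < 55
  expect_lt(mean(tm2$theta_deg[sel2]), 3)
})

test_that("theta never leaves [0, 90] (property sweep)", {
  for (s in 1:20) {
    set.seed(s)
    img <- matrix(runif(48 * 48, 0, 100), 48, 48)
    om <- structure_tensor_orientation(img, sigma_window = 2)
    tm <- theta_map(om, c(runif(1, 5, 44), runif(1, 5, 44)),
                    coherency_min = 0)
    th <- tm$theta_deg[tm$valid]
    expect_gte(min(th), 0)
    expect_lte(max(th), 90)
  }
})

test_that("theta is invariant under rotation about the wound centre", {
  H <- 96; ctr <- c(48.5, 48.5)
  D <- sqrt(outer((1:H - ctr[1])^2, (1:H - ctr[2])^2, `+`))
  rings <- 50 + 50 * sin(D * 1.1)
  rot <- t(rings)[, H:1]   # 90-degree rotation preserves the pattern centre
  t1 <- theta_map(structure_tensor_orientation(rings), ctr)
  t2 <- theta_map(structure_tensor_orientation(rot), ctr)
  sel <- t1$valid & t2$valid & D > 12 & D < 40
  expect_lt(abs(mean(t1$theta_deg[sel]) - mean(t2$theta_deg[sel])), 1)
})

test_that("sector statistics separate orthoradial, radial and random fields", {
  px <- 0.08
  geom <- movie_geometry(200, 200, 1, px, 1, background = 5)
  ctr <- c(100, 100)
  sect <- sector_spec(ctr, radii_um = c(1, 4, 6, 8), pixel_size_um = px)
  run <- function(mode, jitter) {
    res <- generate_filament_image(
      filament_params(mode, centre = ctr, n_filaments = 250,
                      filament_length_px = 12, jitter_deg = jitter),
      geom, 33)
    om <- structure_tensor_orientation(res$image)
    sector_stats(theta_map(om, ctr), sect)
  }
  so <- run("orthoradial", 5)
  expect_gte(so$mean_theta_deg[1], 80)
  sr <- run("radial", 5)
  expect_lte(max(sr$mean_theta_deg), 10)
  expect_true(all(so$n > 0))
})

test_that("uniform random orientations average to theta = 45", {
  # pixels on one filament share its angle, so a single field scatters by
  # +/-3 degrees; pool independent fields for an effective n in the 1000s
  H <- 220; ctr <- c(110, 110); px <- 0.08
  sect <- sector_spec(ctr, radii_um = c(1, 4, 6, 8), pixel_size_um = px)
  sums <- c(0, 0, 0); ns <- c(0, 0, 0)
  for (s in 101:110) {
    res <- generate_filament_image(
      filament_params("uniform_random", n_filaments = 2000,
                      filament_length_px = 6),
      movie_geometry(H, H, 1, px, 1, background = 5), s)
    tm <- theta_map(structure_tensor_orientation(res$image), ctr)
    idx <- wormwound:::sector_indices(tm, sect)
    for (k in 1:3) {
      sums[k] <- sums[k] + sum(tm$theta_deg[idx[[k]]])
      ns[k] <- ns[k] + length(idx[[k]])
    }
  }
  expect_gt(min(ns), 1e4)
  for (k in 1:3) expect_lt(abs(sums[k] / ns[k] - 45), 2)
})

test_that("before/after permutation test behaves at both extremes", {
  px <- 0.08
  geom <- movie_geometry(160, 160, 1, px, 1, background = 5)
  ctr <- c(80, 80)
  sect <- sector_spec(ctr, radii_um = c(0.5, 3, 5, 7), pixel_size_um = px)
  mk <- function(mode, seed) {
    res <- generate_filament_image(
      filament_params(mode, centre = ctr, n_filaments = 220,
                      filament_length_px = 12, jitter_deg = 5), geom, seed)
    theta_map(structure_tensor_orientation(res$image), ctr)
  }
  t_orth <- mk("orthoradial", 35)
  # identical maps: p near 1
  same <- compare_before_after(t_orth, t_orth, sect, n_permutations = 500,
                               seed = 1)
  expect_gte(min(same$p_value, na.rm = TRUE), 0.9)
  # orthoradial vs radial: clearly separated in R1
  t_rad <- mk("radial", 36)
  diff <- compare_before_after(t_orth, t_rad, sect, n_permutations = 1000,
                               seed = 1)
  expect_lt(diff$p_value[1], 0.01)
  # deterministic given the seed
  diff2 <- compare_before_after(t_orth, t_rad, sect, n_permutations = 1000,
                                seed = 1)
  expect_identical(diff$p_value, diff2$p_value)
})

test_that("sector mean theta is robust to 2x downsampling", {
  # filaments wide enough (sigma 2 px) to stay resolved after downsampling
  px <- 0.08
  geom <- movie_geometry(200, 200, 1, px, 1, background = 5)
  ctr <- c(100, 100)
  res <- generate_filament_image(
    filament_params("orthoradial", centre = ctr, n_filaments = 300,
                    filament_length_px = 16, jitter_deg = 5,
                    psf_sigma_px = 2), geom, 37)
  om1 <- structure_tensor_orientation(res$image)
  st1 <- sector_stats(theta_map(om1, ctr),
                      sector_spec(ctr, c(1, 4, 6, 8), px))
  down <- as.matrix(EBImage::resize(res$image, 100, 100))  # antialiased 2x
  om2 <- structure_tensor_orientation(down)   # estimator defaults at both scales
  st2 <- sector_stats(theta_map(om2, ctr / 2),
                      sector_spec(ctr / 2, c(1, 4, 6, 8), px * 2))
  expect_lt(max(abs(st1$mean_theta_deg - st2$mean_theta_deg), na.rm = TRUE), 5)
})
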