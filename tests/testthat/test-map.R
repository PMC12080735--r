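test_that("recentering translates the grid exactly (index-shift oracle)", {
  set.seed(101)
  g <- matrix(runif(200 * 200, 0, 150), 200, 200)
  m <- rnflt_map(g, onh_center = c(90, 105))
  r <- recenter_map(m)
  expect_equal(r$onh_center, c(100, 100))
  # value previously at (x=90, y=105) is now at (100, 100)
  expect_identical(r$grid[100, 100], g[105, 90])
  # full-grid oracle: out[y + dy, x + dx] == in[y, x]
  dx <- 10; dy <- -5
  oracle <- matrix(0, 200, 200)
  for (y in 1:200) for (x in 1:200) {
    yy <- y + dy; xx <- x + dx
    if (yy >= 1 && yy <= 200 && xx >= 1 && xx <= 200) {
      oracle[yy, xx] <- g[y, x]
    }
  }
  expect_equal(r$grid, oracle)
  # identity when already centred
  m0 <- rnflt_map(g, onh_center = c(100, 100))
  expect_identical(recenter_map(m0)$grid, g)
  # excessive shift errors
  expect_error(recenter_map(rnflt_map(g, onh_center = c(2, 100)),
                            target = c(150, 100)),
               "half the grid")
})

test_that("left-eye flip mirrors geometry: profile reflects as 180 - theta", {
  cfg <- noise_free_config()
  co <- generate_cohort(cohort_config(n_subjects = 1, noise_sd = 0,
                                      seed = 21))
  m <- co$map[[1]]
  m$laterality <- "left"
  flipped <- flip_to_right_eye(m)
  expect_equal(flipped$laterality, "right")
  expect_identical(flip_to_right_eye(flipped)$grid, flipped$grid)
  p_orig <- resample_circumpapillary(co$map[[1]], 1.7)
  p_flip <- resample_circumpapillary(flipped, 1.7)
  refl <- rnfltnorm:::interp_profile(p_orig$thickness_um, 0.5,
                                     (180 - p_flip$angle_deg) %% 360)
  expect_equal(p_flip$thickness_um, refl, tolerance = 0.5)
  # mirroring twice restores the interior of the grid
  m2 <- flipped; m2$laterality <- "left"
  twice <- flip_to_right_eye(m2)
  expect_equal(twice$grid[, 2:199], m$grid[, 2:199], tolerance = 1e-12)
})

test_that("circumpapillary resampling is exact on constant and affine maps", {
  m <- rnflt_map(matrix(100, 200, 200))
  p <- resample_circumpapillary(m, 1.7)
  expect_equal(nrow(p), 720)
  expect_equal(p$thickness_um, rep(100, 720), tolerance = 1e-12)
  # bilinear interpolation reproduces an affine field exactly on the circle
  a <- 30; b <- 0.2; cc <- 0.1
  xs <- matrix(seq_len(200), 200, 200, byrow = TRUE)
  ys <- matrix(seq_len(200), 200, 200)
  m2 <- rnflt_map(a + b * xs + cc * ys)
  p2 <- resample_circumpapillary(m2, 1.7)
  r_px <- 1.7 * 200 / 6
  th <- p2$angle_deg * pi / 180
  closed <- a + b * (100 - r_px * cos(th)) + cc * (100 - r_px * sin(th))
  expect_equal(p2$thickness_um, closed, tolerance = 1e-9)
})

test_that("resampling geometry: 0 deg lies temporal-ward of the centre", {
  # mark a single bright column left of centre and confirm the 0-deg
  # sample (9 o'clock) reads it at radius * px_per_mm = 56.67 px
  g <- matrix(0, 200, 200)
  x_t <- 100 - 1.7 * 200 / 6 # 43.33 px
  g[, 43:44] <- 100
  m <- rnflt_map(g)
  p <- resample_circumpapillary(m, 1.7)
  expect_gt(p$thickness_um[p$angle_deg == 0], 50)
  expect_equal(p$thickness_um[p$angle_deg == 180], 0)
  # an angle-only field comes back as that function of angle
  xs <- matrix(seq_len(200), 200, 200, byrow = TRUE)
  ys <- matrix(seq_len(200), 200, 200)
  theta <- (180 - atan2(100 - ys, xs - 100) * 180 / pi) %% 360
  m2 <- rnflt_map(80 + 20 * cos(theta * pi / 180))
  p2 <- resample_circumpapillary(m2, 1.7)
  expect_equal(p2$thickness_um,
               80 + 20 * cos(p2$angle_deg * pi / 180), tolerance = 0.05)
  # circle leaving the grid errors
  expect_error(resample_circumpapillary(m, 3.5), "leaves")
})

test_that("FOA angle matches the arctangent oracle and sign convention", {
  # fovea displaced horizontally, same row: 0 deg
  expect_equal(compute_foa(foa_landmarks(c(40, 100), c(100, 100))), 0)
  # fovea 45 deg below horizontal: -45
  expect_equal(compute_foa(foa_landmarks(c(40, 160), c(100, 100))), -45)
  # arbitrary pairs vs explicit y-down-aware arctangent
  set.seed(7)
  for (i in 1:25) {
    o <- runif(2, 60, 140)
    f <- o + c(sample(c(-1, 1), 1) * runif(1, 20, 60), runif(1, -40, 40))
    expect_equal(compute_foa(foa_landmarks(f, o)),
                 atan2(o[2] - f[2], abs(f[1] - o[1])) * 180 / pi)
  }
  expect_error(compute_foa(foa_landmarks(c(50, 50), c(50, 80))), "vertical")
  expect_error(foa_landmarks(c(50, 50), c(50, 50)), "coincide")
})

test_that("FOA alignment equals rotating the map about the ONH centre", {
  co <- generate_cohort(cohort_config(n_subjects = 1, noise_sd = 0,
                                      seed = 31))
  m <- co$map[[1]]
  p <- resample_circumpapillary(m, 1.7)
  for (foa in c(-10.47, 6, -25)) {
    aligned <- align_foa(p, foa)
    oracle <- resample_circumpapillary(rotate_map_oracle(m, foa), 1.7)
    expect_equal(aligned$thickness_um, oracle$thickness_um, tolerance = 0.6)
    # rotated landmarks read FOA 0
    lm <- foa_landmarks(c(100 - 150, 100 - 150 * tan(foa * pi / 180)),
                        c(100, 100))
    expect_equal(compute_foa(lm), foa, tolerance = 1e-9)
    expect_equal(compute_foa(rotate_landmarks(lm, foa)), 0,
                 tolerance = 1e-9)
  }
  # identity and inverse
  expect_profiles_equal(align_foa(p, 0), p)
  back <- align_foa(align_foa(p, 12.3), -12.3)
  expect_equal(back$thickness_um, p$thickness_um, tolerance = 0.2)
})

test_that("clock hours follow the TSNIT convention and partition the circle", {
  expect_equal(clock_hour_of(0), 9L)
  expect_equal(clock_hour_of(90), 12L)
  expect_equal(clock_hour_of(180), 3L)
  expect_equal(clock_hour_of(270), 6L)
  expect_equal(clock_hour_of(359), 9L)
  angles <- seq(0, 359.5, by = 0.5)
  ch <- clock_hour_of(angles)
  expect_true(all(table(ch) == 60)) # 12 sectors x 60 samples each
  # meridian-start convention shifts membership
  expect_equal(clock_hour_of(0, centered = FALSE), 9L)
  expect_equal(clock_hour_of(29.5, centered = FALSE), 9L)
})

test_that("sector means equal the brute-force index-set oracle", {
  p <- new_profile_for_test <- {
    set.seed(12)
    rnfltnorm:::new_profile(runif(720, 20, 140))
  }
  for (ch in 1:12) {
    centre <- clock_hour_centers()$center_deg[
      clock_hour_centers()$ch == ch]
    dd <- (p$angle_deg - centre + 180) %% 360 - 180
    idx <- which(dd >= -15 & dd < 15)
    expect_length(idx, 60)
    expect_equal(sector_mean(p, ch), mean(p$thickness_um[idx]))
  }
  flat <- rnfltnorm:::new_profile(rep(80, 720))
  expect_true(all(vapply(1:12, sector_mean, numeric(1),
                         profile = flat) == 80))
  # indicator of CH12 sector
  ind <- rnfltnorm:::new_profile(
    ifelse(clock_hour_of(seq(0, 359.5, 0.5)) == 12, 100, 0))
  expect_equal(sector_mean(ind, 12), 100)
  expect_equal(sector_mean(ind, 3), 0)
})
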