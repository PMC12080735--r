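bar_mask <- function(rows, cols, n = 200) {
  g <- matrix(0L, n, n)
  g[rows, cols] <- 1L
  g
}

test_that("width filtering keeps thick bars and drops thin ones", {
  g <- bar_mask(40:45, 20:120) | bar_mask(100:101, 20:120) # widths 6 and 2
  vm <- vessel_mask(g + 0L)
  kept <- retain_thick_vessels(vm, min_width_px = 4)
  expect_true(all(kept$grid[40:45, 20:120] == 1))
  expect_true(all(kept$grid[100:101, ] == 0))
  # survivors are reconstructed whole, not eroded
  expect_equal(sum(kept$grid), 6 * 101)
})

test_that("surviving components match a distance-transform width oracle", {
  widths <- c(2, 3, 4, 5, 6, 8)
  g <- matrix(0L, 200, 200)
  tops <- seq(10, by = 25, length.out = length(widths))
  for (i in seq_along(widths)) {
    g[tops[i]:(tops[i] + widths[i] - 1), 15:180] <- 1L
  }
  kept <- retain_thick_vessels(vessel_mask(g), min_width_px = 4)
  labels <- EBImage::bwlabel(g)
  dist <- EBImage::distmap(g)
  for (i in seq_along(widths)) {
    comp <- labels == i
    survives <- any(kept$grid[comp] == 1)
    oracle <- 2 * max(dist[comp]) > 4 # local width > 4 px
    expect_equal(survives, oracle, info = paste("width", widths[i]))
  }
})

test_that("thinning reduces a bar to its centerline and is stable", {
  vm <- vessel_mask(bar_mask(48:52, 20:80))
  sk <- skeletonize_mask(vm)
  px <- which(sk$grid == 1, arr.ind = TRUE)
  expect_gt(nrow(px), 40)
  expect_true(all(px[, "row"] == 50)) # medial axis of a width-5 bar
  # an already-thin line is unchanged
  thin <- vessel_mask(bar_mask(50, 20:80))
  expect_identical(skeletonize_mask(thin)$grid, thin$grid)
  # empty stays empty
  empty <- vessel_mask(matrix(0L, 50, 50), onh_center = c(25, 25))
  expect_identical(skeletonize_mask(empty)$grid, empty$grid)
})

test_that("mean vessel angle matches a brute-force pixel scan", {
  co <- generate_cohort(cohort_config(n_subjects = 1, noise_sd = 0,
                                      seed = 12))
  set.seed(1)
  vm <- generate_vessel_skeleton(co$map[[1]], 75, 300,
                                 angular_offset_sd = 0)
  got <- mean_vessel_angle(vm, 1.7, window = c(0, 110),
                           annulus_halfwidth_px = 2)
  # independent scan over all pixels
  idx <- which(vm$grid == 1, arr.ind = TRUE)
  dx <- idx[, "col"] - 100; dy <- idx[, "row"] - 100
  r <- sqrt(dx^2 + dy^2)
  th <- (180 - atan2(-dy, dx) * 180 / pi) %% 360
  sel <- abs(r - 1.7 * 200 / 6) <= 2 & th >= 0 & th <= 110
  expect_equal(got, mean(th[sel]))
  expect_equal(got, 75, tolerance = 0.5)
  # two rays crossing the annulus at 70 and 80 average to 75
  g <- rnfltnorm:::rasterize_ray(200, c(100, 100), 70, 200 / 6, 1, 2.3) |
    rnfltnorm:::rasterize_ray(200, c(100, 100), 80, 200 / 6, 1, 2.3)
  two <- vessel_mask(g + 0L)
  expect_equal(mean_vessel_angle(two, 1.7, c(0, 110)), 75, tolerance = 0.5)
})

test_that("rotating a vessel mask shifts its mean angle accordingly", {
  g <- rnfltnorm:::rasterize_ray(200, c(100, 100), 70, 200 / 6, 1, 2.3)
  base <- mean_vessel_angle(vessel_mask(g + 0L), 1.7, c(0, 110))
  # rotate pixel positions by +15 deg (TSNIT), i.e. rebuild the ray there
  g2 <- rnfltnorm:::rasterize_ray(200, c(100, 100), 85, 200 / 6, 1, 2.3)
  shifted <- mean_vessel_angle(vessel_mask(g2 + 0L), 1.7, c(0, 110))
  expect_equal(shifted - base, 15, tolerance = 1)
})

test_that("vessel mean locations correlate with peak locations", {
  cfg <- cohort_config(n_subjects = 120, seed = 321)
  co <- generate_cohort(cfg, vessels = TRUE, vessel_offset_sd = 8)
  angles <- purrr::map_dfr(seq_len(nrow(co)), function(i) {
    tibble::tibble(
      st_vessel = mean_vessel_angle(co$vessel_mask[[i]], 1.7, c(0, 180),
                                    annulus_halfwidth_px = 2),
      it_vessel = mean_vessel_angle(co$vessel_mask[[i]], 1.7, c(180, 360),
                                    annulus_halfwidth_px = 2)
    )
  })
  r_st <- correlate_vessels_with_peaks(
    tibble::tibble(vessel_angle_deg = angles$st_vessel,
                   peak_angle_deg = co$true_st_peak))
  r_it <- correlate_vessels_with_peaks(
    tibble::tibble(vessel_angle_deg = angles$it_vessel,
                   peak_angle_deg = co$true_it_peak))
  expect_gt(abs(r_st$r), 0.5)
  expect_gt(abs(r_it$r), 0.5)
  expect_lt(r_st$p_value, 0.001)
  # perfectly collocated vessels: r = 1
  ident <- tibble::tibble(vessel_angle_deg = co$true_st_peak,
                          peak_angle_deg = co$true_st_peak)
  expect_equal(correlate_vessels_with_peaks(ident)$r, 1)
  const <- tibble::tibble(vessel_angle_deg = rep(70, 10),
                          peak_angle_deg = co$true_st_peak[1:10])
  expect_error(correlate_vessels_with_peaks(const), "constant")
})
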