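#' Synthetic-cohort configuration
#'
#' Parameters of the simulated normative cohort. Peak-location and
#' fovea-ONH-angle distributions default to values representative of a
#' healthy adult population at the 1.7 mm scan circle: supratemporal peaks
#' N(70.5, 10.38^2) deg, infratemporal peaks N(281.0, 12.36^2) deg, FOA
#' N(-10.47, 5.44^2) deg. Profile shape parameters (baseline, bump
#' amplitude/width, noise) are the generator's own model of the
#' double-humped TSNIT morphology.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param st_peak_mean,st_peak_sd ST peak location distribution (deg);
#'   mean must lie in the ST window `[0, 110]`.
#' @param it_peak_mean,it_peak_sd IT peak location distribution (deg);
#'   mean must lie in the IT window `[250, 360]`.
#' @param foa_mean,foa_sd Fovea-ONH axis angle distribution (deg).
#' @param peak_amplitude_mean,peak_amplitude_sd Bump amplitude above
#'   baseline (micrometres).
#' @param baseline_thickness Angle-independent floor thickness (um).
#' @param noise_sd SD of i.i.d. additive Gaussian noise per angular sample
#'   (um); samples are floored at 0.
#' @param bump_width Wrapped-Gaussian bump SD (deg), > 0.
#' @param seed RNG seed for [generate_cohort()].
#' @param grid_size Map side length in pixels (default 200).
#' @param px_per_mm Map pixel pitch (default 200/6).
#' @param radius_mm Primary scan-circle radius (default 1.7).
#' @param step_deg Angular sampling step (default 0.5).
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 78,
                          st_peak_mean = 70.5, st_peak_sd = 10.38,
                          it_peak_mean = 281.0, it_peak_sd = 12.36,
                          foa_mean = -10.47, foa_sd = 5.44,
                          peak_amplitude_mean = 100, peak_amplitude_sd = 15,
                          baseline_thickness = 40, noise_sd = 4,
                          bump_width = 23, seed = NULL,
                          grid_size = 200, px_per_mm = 200 / 6,
                          radius_mm = 1.7, step_deg = 0.5) {
  if (n_subjects < 1) abort("`n_subjects` must be >= 1.")
  sds <- c(st_peak_sd, it_peak_sd, foa_sd, peak_amplitude_sd, noise_sd)
  if (any(sds < 0)) abort("standard deviations must be >= 0.")
  if (st_peak_mean < 0 || st_peak_mean > 110) {
    abort("`st_peak_mean` must lie in [0, 110].")
  }
  if (it_peak_mean < 250 || it_peak_mean > 360) {
    abort("`it_peak_mean` must lie in [250, 360].")
  }
  if (bump_width <= 0) abort("`bump_width` must be > 0.")
  structure(
    list(n_subjects = as.integer(n_subjects),
         st_peak_mean = st_peak_mean, st_peak_sd = st_peak_sd,
         it_peak_mean = it_peak_mean, it_peak_sd = it_peak_sd,
         foa_mean = foa_mean, foa_sd = foa_sd,
         peak_amplitude_mean = peak_amplitude_mean,
         peak_amplitude_sd = peak_amplitude_sd,
         baseline_thickness = baseline_thickness,
         noise_sd = noise_sd, bump_width = bump_width, seed = seed,
         grid_size = as.integer(grid_size), px_per_mm = px_per_mm,
         radius_mm = radius_mm, step_deg = step_deg),
    class = "cohort_config"
  )
}

# Wrapped (circular) Gaussian bump, unit height at delta = 0.
wrapped_gaussian <- function(delta_deg, sd_deg) {
  d <- (delta_deg + 180) %% 360 - 180
  exp(-d^2 / (2 * sd_deg^2)) +
    exp(-(d - 360)^2 / (2 * sd_deg^2)) +
    exp(-(d + 360)^2 / (2 * sd_deg^2))
}

# Closed-form noise-free thickness at arbitrary angles.
profile_shape <- function(angle_deg, st_peak, it_peak, amp_st, amp_it,
                          baseline, bump_width) {
  baseline +
    amp_st * wrapped_gaussian(angle_deg - st_peak, bump_width) +
    amp_it * wrapped_gaussian(angle_deg - it_peak, bump_width)
}

#' Generate one synthetic TSNIT profile
#'
#' Double-humped thickness profile: a constant baseline plus wrapped
#' Gaussian bumps at the requested ST and IT peak angles, plus i.i.d.
#' Gaussian noise per angular sample (floored at 0 um). With zero noise the
#' window argmax recovers each requested peak to grid resolution. Uses the
#' current RNG state; seed outside for reproducibility.
#'
#' @param config A [cohort_config] supplying shape and noise parameters.
#' @param st_peak ST peak angle in `[0, 110]` deg.
#' @param it_peak IT peak angle in `[250, 360]` deg.
#' @param amp_st,amp_it Bump amplitudes (um); default the configured mean.
#' @return A profile tibble (`angle_deg`, `thickness_um`).
#' @export
generate_profile <- function(config, st_peak, it_peak,
                             amp_st = config$peak_amplitude_mean,
                             amp_it = config$peak_amplitude_mean) {
  stopifnot(inherits(config, "cohort_config"))
  if (st_peak < 0 || st_peak > 110) {
    abort("`st_peak` outside the supratemporal window [0, 110].")
  }
  if (it_peak < 250 || it_peak > 360) {
    abort("`it_peak` outside the infratemporal window [250, 360].")
  }
  angles <- seq(0, 360 - config$step_deg, by = config$step_deg)
  v <- profile_shape(angles, st_peak, it_peak, amp_st, amp_it,
                     config$baseline_thickness, config$bump_width)
  if (config$noise_sd > 0) {
    v <- v + rnorm(length(v), 0, config$noise_sd)
  }
  new_profile(pmax(v, 0), step_deg = config$step_deg,
              radius_mm = config$radius_mm)
}

# Draw from N(mean, sd) truncated to [lo, hi] by redrawing.
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(mean, n))
  out <- rnorm(n, mean, sd)
  bad <- which(out < lo | out > hi)
  while (length(bad) > 0) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(out < lo | out > hi)
  }
  out
}

# Rasterize a subject profile onto an annular map. Inside the annulus
# (1.0-2.4 mm) the pixel value is the circular linear interpolation of the
# profile at the pixel's TSNIT angle; a cosine taper over 0.3 mm takes the
# map smoothly to zero outside, so every supported scan radius
# (1.3-2.1 mm) sees the pure angular profile.
profile_to_map <- function(profile, config) {
  n <- config$grid_size
  cx <- 100; cy <- 100
  x <- matrix(seq_len(n), n, n, byrow = TRUE)
  y <- matrix(seq_len(n), n, n)
  dx <- x - cx
  dy <- y - cy
  r_mm <- sqrt(dx^2 + dy^2) / config$px_per_mm
  # TSNIT angle: standard y-up angle alpha, theta = 180 - alpha
  theta <- (180 - atan2(cy - y, dx) * 180 / pi) %% 360
  v <- interp_profile(profile$thickness_um, profile_step(profile), theta)
  w <- radial_window(r_mm, 1.0, 2.4, 0.3)
  rnflt_map(matrix(v * w, n, n), px_per_mm = config$px_per_mm,
            onh_center = c(cx, cy), laterality = "right")
}

radial_window <- function(r, lo, hi, taper) {
  w <- numeric(length(r))
  w[r >= lo & r <= hi] <- 1
  ramp_in <- r > lo - taper & r < lo
  w[ramp_in] <- 0.5 * (1 + cos(pi * (lo - r[ramp_in]) / taper))
  ramp_out <- r > hi & r < hi + taper
  w[ramp_out] <- 0.5 * (1 + cos(pi * (r[ramp_out] - hi) / taper))
  dim(w) <- dim(r)
  w
}

#' Generate a synthetic normative cohort
#'
#' Draws per-subject ST/IT peak locations (truncated-normal within their
#' windows: out-of-window draws are redrawn, not clamped), bump amplitudes,
#' FOA angles and noise, builds each subject's TSNIT profile and an
#' ONH-centered thickness map whose circumpapillary resampling reproduces
#' that profile, and places fovea/ONH landmarks realizing the drawn FOA.
#' Deterministic given `config$seed`.
#'
#' @param config A [cohort_config].
#' @param vessels Also draw a synthetic vessel skeleton per subject
#'   (default FALSE); see [generate_vessel_skeleton()].
#' @param vessel_offset_sd Angular SD (deg) of the vessel offset from the
#'   true peak, used when `vessels = TRUE`.
#' @return A cohort tibble with one row per subject: `subject_id`,
#'   `true_st_peak`, `true_it_peak`, `amp_st`, `amp_it`, `foa_deg`,
#'   `profile` (list of tibbles), `map` (list of [rnflt_map]), `landmarks`
#'   (list of [foa_landmarks]) and, if requested, `vessel_mask`.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_subjects = 3, seed = 7))
#' cohort
#' @export
generate_cohort <- function(config, vessels = FALSE, vessel_offset_sd = 8) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_subjects
  st <- rtrunc_norm(n, config$st_peak_mean, config$st_peak_sd, 0, 110)
  it <- rtrunc_norm(n, config$it_peak_mean, config$it_peak_sd, 250, 360)
  amp_st <- rtrunc_norm(n, config$peak_amplitude_mean,
                        config$peak_amplitude_sd, 1e-6, Inf)
  amp_it <- rtrunc_norm(n, config$peak_amplitude_mean,
                        config$peak_amplitude_sd, 1e-6, Inf)
  foa <- rnorm(n, config$foa_mean, config$foa_sd)
  rows <- purrr::map(seq_len(n), function(i) {
    prof <- generate_profile(config, st[i], it[i], amp_st[i], amp_it[i])
    map <- profile_to_map(prof, config)
    # fovea 4.5 mm temporal-ward of the ONH along the drawn FOA
    lx <- 4.5 * config$px_per_mm
    lm <- foa_landmarks(
      fovea_xy = c(100 - lx, 100 - lx * tan(foa[i] * pi / 180)),
      onh_xy = c(100, 100)
    )
    vm <- if (vessels) {
      generate_vessel_skeleton(map, st[i], it[i],
                               angular_offset_sd = vessel_offset_sd)
    } else NULL
    list(profile = prof, map = map, landmarks = lm, vessel_mask = vm)
  })
  out <- tibble(
    subject_id = sprintf("subj_%03d", seq_len(n)),
    true_st_peak = st, true_it_peak = it,
    amp_st = amp_st, amp_it = amp_it, foa_deg = foa,
    profile = purrr::map(rows, "profile"),
    map = purrr::map(rows, "map"),
    landmarks = purrr::map(rows, "landmarks")
  )
  if (vessels) out$vessel_mask <- purrr::map(rows, "vessel_mask")
  out
}

#' Draw a synthetic vessel skeleton for one subject
#'
#' Places one-pixel-wide radial polylines at the subject's ST and IT peak
#' angles plus independent Gaussian angular offsets, spanning the
#' 1.0-2.3 mm annulus, emulating the major vessels that run close to the
#' nerve-fiber bundles. Uses the current RNG state.
#'
#' @param map An [rnflt_map] (supplies geometry).
#' @param st_peak,it_peak The subject's peak angles (deg).
#' @param angular_offset_sd SD of the vessel-to-peak angular offset (deg);
#'   0 places vessels exactly at the peaks.
#' @param width_px Drawn vessel width (default 1 = skeleton; larger values
#'   give thick vessels for testing the width filter).
#' @return A [vessel_mask].
#' @export
generate_vessel_skeleton <- function(map, st_peak, it_peak,
                                     angular_offset_sd = 8, width_px = 1) {
  stopifnot(inherits(map, "rnflt_map"))
  ang <- c(st_peak + rnorm(1, 0, angular_offset_sd),
           it_peak + rnorm(1, 0, angular_offset_sd))
  n <- nrow(map$grid)
  g <- matrix(0L, n, n)
  for (a in ang) {
    g <- g | rasterize_ray(n, map$onh_center, a, map$px_per_mm,
                           r_lo_mm = 1.0, r_hi_mm = 2.3,
                           width_px = width_px)
  }
  vessel_mask(g + 0L, onh_center = map$onh_center,
              px_per_mm = map$px_per_mm)
}

rasterize_ray <- function(n, center, angle_deg, px_per_mm,
                          r_lo_mm, r_hi_mm, width_px = 1) {
  d <- tsnit_direction(angle_deg)
  r_px <- seq(r_lo_mm * px_per_mm, r_hi_mm * px_per_mm, by = 0.25)
  x <- round(center[1] + r_px * d[, "dx"])
  y <- round(center[2] + r_px * d[, "dy"])
  g <- matrix(0L, n, n)
  half <- floor((width_px - 1) / 2)
  extra <- width_px - 1 - half
  # thicken perpendicular to the ray
  px <- -d[, "dy"]; py <- d[, "dx"]
  for (k in seq(-half, extra)) {
    xx <- round(x + k * px); yy <- round(y + k * py)
    ok <- xx >= 1 & xx <= n & yy >= 1 & yy <= n
    g[cbind(yy[ok], xx[ok])] <- 1L
  }
  g
}
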