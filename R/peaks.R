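#' Peak-analysis configuration
#'
#' Holds the angular windows in which the supratemporal (ST) and
#' infratemporal (IT) RNFLT peaks are sought, the scan-circle radii at which
#' profiles are read, and the hemisphere boundary used by the warp.
#'
#' @param st_window ST search window in degrees (default `c(0, 110)`),
#'   within the superior hemisphere.
#' @param it_window IT search window in degrees (default `c(250, 360)`),
#'   within the inferior hemisphere.
#' @param hemisphere_boundary Superior/inferior boundary (default 180).
#' @param radii_mm Scan-circle radii in millimetres.
#' @param primary_radius_mm The radius used for normalization (default 1.7);
#'   must be one of `radii_mm`.
#' @param step_deg Angular sampling step (default 0.5).
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(st_window = c(0, 110),
                            it_window = c(250, 360),
                            hemisphere_boundary = 180,
                            radii_mm = c(1.3, 1.5, 1.7, 1.9, 2.1),
                            primary_radius_mm = 1.7,
                            step_deg = 0.5) {
  if (st_window[1] < 0 || st_window[2] > hemisphere_boundary) {
    abort("`st_window` must lie within the superior hemisphere.")
  }
  if (it_window[1] < hemisphere_boundary || it_window[2] > 360) {
    abort("`it_window` must lie within the inferior hemisphere.")
  }
  if (!primary_radius_mm %in% radii_mm) {
    abort("`primary_radius_mm` must be one of `radii_mm`.")
  }
  structure(
    list(st_window = st_window, it_window = it_window,
         hemisphere_boundary = hemisphere_boundary,
         radii_mm = sort(radii_mm), primary_radius_mm = primary_radius_mm,
         step_deg = step_deg),
    class = "analysis_config"
  )
}

# Indices of profile samples inside a window, inclusive at both ends.
# A window ending at 360 also admits the 0-deg sample, reported as 360.
window_samples <- function(profile, window) {
  a <- profile$angle_deg
  sel <- which(a >= window[1] & a <= window[2])
  ang <- a[sel]
  if (window[2] >= 360 && window[1] > 0) {
    sel <- c(sel, which(a == 0))
    ang <- c(ang, 360)
  }
  ord <- order(ang)
  list(idx = sel[ord], angle = ang[ord])
}

#' Detect the supratemporal and infratemporal RNFLT peaks
#'
#' The ST peak is the thickest sample with angle in `st_window` (default
#' 0-110 deg) and the IT peak the thickest in `it_window` (default 250-360
#' deg), both bounds inclusive, on the profile's own angular grid (no
#' sub-sample refinement). Ties are broken toward the smaller angle. A
#' window whose samples are all equal is flagged degenerate and reports the
#' window's smallest angle.
#'
#' @param profile A profile tibble (`angle_deg`, `thickness_um`).
#' @param config An [analysis_config].
#' @return A one-row tibble: `st_angle_deg`, `st_amp_um`, `it_angle_deg`,
#'   `it_amp_um`, `degenerate` (TRUE if either window was flat).
#' @examples
#' cfg <- cohort_config(n_subjects = 1, noise_sd = 0, seed = 1)
#' p <- generate_profile(cfg, st_peak = 70.5, it_peak = 281)
#' detect_peaks(p)
#' @export
detect_peaks <- function(profile, config = analysis_config()) {
  check_profile(profile)
  st <- window_argmax(profile, config$st_window)
  it <- window_argmax(profile, config$it_window)
  tibble(
    st_angle_deg = st$angle, st_amp_um = st$amp,
    it_angle_deg = it$angle, it_amp_um = it$amp,
    degenerate = st$degenerate || it$degenerate
  )
}

window_argmax <- function(profile, window) {
  w <- window_samples(profile, window)
  v <- profile$thickness_um[w$idx]
  flat <- diff(range(v)) == 0
  i <- which.max(v) # first maximum == smallest angle (angles sorted)
  list(angle = w$angle[i], amp = v[i], degenerate = flat)
}

#' Peak locations across several scan-circle radii
#'
#' Resamples the map at each radius and detects the ST/IT peaks on each
#' profile, to examine how scan-circle diameter moves the peaks.
#'
#' @param map An [rnflt_map].
#' @param config An [analysis_config]; its `radii_mm` are used.
#' @return A tibble with one row per radius: `radius_mm`, `st_angle_deg`,
#'   `st_amp_um`, `it_angle_deg`, `it_amp_um`, `degenerate`.
#' @export
peaks_across_radii <- function(map, config = analysis_config()) {
  stopifnot(inherits(map, "rnflt_map"))
  purrr::map_dfr(config$radii_mm, function(r) {
    p <- resample_circumpapillary(map, radius_mm = r,
                                  step_deg = config$step_deg)
    dplyr::bind_cols(tibble(radius_mm = r), detect_peaks(p, config))
  })
}

#' Detect peaks for every subject of a cohort
#'
#' @param cohort A cohort tibble with a `profile` list-column (see
#'   [generate_cohort()]) and a `subject_id` column.
#' @param config An [analysis_config].
#' @return A tibble with one row per subject: `subject_id` plus the
#'   [detect_peaks()] columns.
#' @export
detect_cohort_peaks <- function(cohort, config = analysis_config()) {
  if (!is.data.frame(cohort) || is.null(cohort$profile)) {
    abort("`cohort` must be a tibble with a `profile` list-column.")
  }
  peaks <- purrr::map_dfr(cohort$profile, detect_peaks, config = config)
  dplyr::bind_cols(tibble(subject_id = cohort$subject_id), peaks)
}
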