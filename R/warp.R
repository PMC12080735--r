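#' Piecewise-linear peak-alignment warp specification
#'
#' A peak-normalizing warp moves a profile's supratemporal peak from
#' `p_st` to the target `m_st` and its infratemporal peak from `p_it` to
#' `m_it`, keeping 0, 180 and 360 degrees fixed. The angular map phi is
#' piecewise linear through `(0,0) (p_st,m_st) (180,180) (p_it,m_it)
#' (360,360)`, so the segment before each peak is compressed or expanded and
#' the segment after it oppositely, hemisphere by hemisphere.
#'
#' @param p_st,p_it The individual's ST / IT peak angles, `p_st` in (0, 180),
#'   `p_it` in (180, 360).
#' @param m_st,m_it Target (cohort mean) peak angles, same open ranges.
#' @return A list of class `warp_spec`.
#' @export
warp_spec <- function(p_st, p_it, m_st, m_it) {
  v <- c(p_st = p_st, p_it = p_it, m_st = m_st, m_it = m_it)
  if (anyNA(v) || !is.numeric(v)) abort("warp knots must be numeric.")
  if (p_st <= 0 || p_st >= 180 || m_st <= 0 || m_st >= 180) {
    abort("ST knots must lie strictly inside (0, 180).")
  }
  if (p_it <= 180 || p_it >= 360 || m_it <= 180 || m_it >= 360) {
    abort("IT knots must lie strictly inside (180, 360).")
  }
  structure(list(p_st = p_st, p_it = p_it, m_st = m_st, m_it = m_it),
            class = "warp_spec")
}

# Inverse angular map: for output angles theta, the input angle phi^{-1}(theta).
warp_inverse <- function(spec, theta_deg) {
  knots_out <- c(0, spec$m_st, 180, spec$m_it, 360)
  knots_in <- c(0, spec$p_st, 180, spec$p_it, 360)
  approx(knots_out, knots_in, xout = theta_deg %% 360, ties = "ordered")$y
}

#' Warp a profile so its peaks land on target locations
#'
#' Evaluates the warped profile on the regular angular grid by pulling each
#' output angle back through the inverse piecewise-linear map and linearly
#' interpolating the input profile there. Values at the anchors 0 and 180
#' degrees (and, by wraparound, 360) are unchanged, and the output value at
#' each target angle equals the input value at the corresponding individual
#' peak, so peak amplitudes are preserved.
#'
#' @param profile A profile tibble (`angle_deg`, `thickness_um`).
#' @param spec A [warp_spec].
#' @return The warped profile tibble, on the same angular grid.
#' @export
warp_profile <- function(profile, spec) {
  check_profile(profile)
  stopifnot(inherits(spec, "warp_spec"))
  step <- profile_step(profile)
  src <- warp_inverse(spec, profile$angle_deg)
  out <- profile
  out$thickness_um <- interp_profile(profile$thickness_um, step, src)
  out
}

#' Cohort mean peak locations
#'
#' Arithmetic means of the detected ST and IT peak angles across subjects;
#' these are the warp targets for peak normalization. Neither window crosses
#' the 0/360 seam, so plain (non-circular) means apply. Subjects flagged
#' with a degenerate (flat-window) peak are excluded.
#'
#' @param peaks A tibble of detected peaks ([detect_cohort_peaks()] output,
#'   or any tibble with `st_angle_deg` and `it_angle_deg`).
#' @return A one-row tibble: `m_st_deg`, `m_it_deg`, `n`.
#' @export
mean_peak_locations <- function(peaks) {
  if (!is.data.frame(peaks) ||
      !all(c("st_angle_deg", "it_angle_deg") %in% names(peaks))) {
    abort("`peaks` needs columns `st_angle_deg` and `it_angle_deg`.")
  }
  if ("degenerate" %in% names(peaks) && any(peaks$degenerate)) {
    n_bad <- sum(peaks$degenerate)
    warn(sprintf("excluding %d subject(s) with degenerate peaks.", n_bad))
    peaks <- peaks[!peaks$degenerate, ]
  }
  if (nrow(peaks) == 0) abort("no usable peaks.")
  tibble(m_st_deg = mean(peaks$st_angle_deg),
         m_it_deg = mean(peaks$it_angle_deg),
         n = nrow(peaks))
}

#' Peak-normalize every profile of a cohort
#'
#' Warps each profile so its detected peaks land on the target locations.
#' By default the targets are snapped to the profiles' angular grid, so
#' every warped profile attains its window maximum at exactly the same
#' sample and the post-normalization spread of detected peak locations is
#' identically zero.
#'
#' @param profiles A list of profile tibbles, or a cohort tibble with a
#'   `profile` list-column (warped profiles are then returned in a
#'   `profile_pn` list-column).
#' @param peaks Peak table aligned with `profiles` (one row each, with
#'   `st_angle_deg`, `it_angle_deg`). If `NULL`, peaks are detected.
#' @param targets One-row tibble with `m_st_deg`, `m_it_deg` (e.g.
#'   [mean_peak_locations()] output). If `NULL`, computed from `peaks`.
#' @param config An [analysis_config].
#' @param snap_to_grid Snap targets to the angular grid (default TRUE).
#' @return Same shape as `profiles`: a list of warped profiles, or the
#'   cohort tibble with an added `profile_pn` list-column.
#' @export
normalize_cohort <- function(profiles, peaks = NULL, targets = NULL,
                             config = analysis_config(),
                             snap_to_grid = TRUE) {
  cohort <- NULL
  if (is.data.frame(profiles)) {
    if (is.null(profiles$profile)) {
      abort("a cohort tibble needs a `profile` list-column.")
    }
    cohort <- profiles
    profiles <- cohort$profile
  }
  if (!is.list(profiles)) abort("`profiles` must be a list of profiles.")
  if (is.null(peaks)) {
    peaks <- purrr::map_dfr(profiles, detect_peaks, config = config)
  }
  if (nrow(peaks) != length(profiles)) {
    abort("`peaks` must have one row per profile.")
  }
  if (is.null(targets)) targets <- mean_peak_locations(peaks)
  m_st <- targets$m_st_deg
  m_it <- targets$m_it_deg
  if (snap_to_grid && length(profiles) > 0) {
    step <- profile_step(profiles[[1]])
    m_st <- round(m_st / step) * step
    m_it <- round(m_it / step) * step
  }
  warped <- purrr::map2(profiles, seq_along(profiles), function(p, i) {
    p_st <- peaks$st_angle_deg[i]
    p_it <- peaks$it_angle_deg[i]
    # a peak sitting exactly on a hemisphere anchor cannot be moved; nudge
    # onto the nearest interior sample so the warp stays monotone
    step <- profile_step(p)
    p_st <- min(max(p_st, step), 180 - step)
    p_it <- min(max(p_it, 180 + step), 360 - step)
    warp_profile(p, warp_spec(p_st, p_it, m_st, m_it))
  })
  if (!is.null(cohort)) {
    cohort$profile_pn <- warped
    cohort
  } else {
    warped
  }
}
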