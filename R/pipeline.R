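#' Run the full peak-normalization analysis on a cohort
#'
#' End-to-end pipeline: resamples each subject's circumpapillary profile
#' from its thickness map at the primary scan radius, detects ST/IT peaks,
#' warps every profile to the cohort mean peak locations, and (optionally)
#' repeats the normalization after rotating each profile so its fovea-ONH
#' axis lies on the horizontal. Clock-hour summary tables, per-clock-hour
#' CoV reductions, paired Wilcoxon tests on the 12 CoV values, and
#' before/after sector categorization against the un-normalized normative
#' range are returned together.
#'
#' @param cohort A cohort tibble ([generate_cohort()] / [read_cohort()]):
#'   needs `map` (list of [rnflt_map]) or `profile`, `subject_id`, and
#'   `foa_deg` or `landmarks` when `foa_align = TRUE`.
#' @param config An [analysis_config].
#' @param foa_align Also compute the FOA-aligned normalization branch
#'   (default TRUE).
#' @param method Normative-limit method, see [build_normative()].
#' @return An object of class `rnflt_pn_analysis`: list with
#'   `sector_tables` (long tibble, `condition` in before/after_pn/
#'   after_pn_foa), `cov_reduction`, `wilcoxon`, `targets`, `targets_foa`,
#'   `normative`, `peaks`, `profiles` (as analyzed), `profiles_pn`
#'   (peak-normalized), `categories_before`, `categories_after`,
#'   `category_changes`, `n`.
#' @examples
#' \donttest{
#' cohort <- generate_cohort(cohort_config(n_subjects = 30, seed = 11))
#' fit <- analyze_cohort(cohort)
#' glance(fit)
#' }
#' @export
analyze_cohort <- function(cohort, config = analysis_config(),
                           foa_align = TRUE,
                           method = c("parametric", "percentile")) {
  method <- match.arg(method)
  if (!is.data.frame(cohort)) abort("`cohort` must be a cohort tibble.")
  profiles <- cohort_profiles(cohort, config)
  n <- length(profiles)
  if (n < 2) abort("need at least 2 subjects.")

  peaks <- purrr::map_dfr(profiles, detect_peaks, config = config)
  peaks <- dplyr::bind_cols(
    tibble(subject_id = cohort$subject_id %||% seq_len(n)), peaks
  )
  targets <- mean_peak_locations(peaks)
  warped <- normalize_cohort(profiles, peaks, targets, config = config)

  tab_before <- sector_table(profiles)
  tab_after <- sector_table(warped)
  sector_tables <- dplyr::bind_rows(
    dplyr::mutate(tab_before, condition = "before"),
    dplyr::mutate(tab_after, condition = "after_pn")
  )
  reduction <- tibble(
    ch = 1:12,
    cov_before = tab_before$cov_pct,
    cov_after_pn = tab_after$cov_pct,
    reduction_pn_pct = safe_cov_reduction(tab_before$cov_pct,
                                          tab_after$cov_pct)
  )
  wilcox <- dplyr::bind_cols(
    tibble(comparison = "before_vs_after_pn"),
    wilcoxon_signed_rank(tab_before$cov_pct, tab_after$cov_pct)
  )

  targets_foa <- NULL
  if (foa_align) {
    foa <- cohort_foa(cohort)
    aligned <- purrr::map2(profiles, foa, align_foa)
    peaks_foa <- purrr::map_dfr(aligned, detect_peaks, config = config)
    targets_foa <- mean_peak_locations(peaks_foa)
    warped_foa <- normalize_cohort(aligned, peaks_foa, targets_foa,
                                   config = config)
    tab_foa <- sector_table(warped_foa)
    sector_tables <- dplyr::bind_rows(
      sector_tables, dplyr::mutate(tab_foa, condition = "after_pn_foa")
    )
    reduction$cov_after_pn_foa <- tab_foa$cov_pct
    reduction$reduction_pn_foa_pct <-
      safe_cov_reduction(tab_before$cov_pct, tab_foa$cov_pct)
    wilcox <- dplyr::bind_rows(
      wilcox,
      dplyr::bind_cols(tibble(comparison = "before_vs_after_pn_foa"),
                       wilcoxon_signed_rank(tab_before$cov_pct,
                                            tab_foa$cov_pct)),
      dplyr::bind_cols(tibble(comparison = "after_pn_vs_after_pn_foa"),
                       wilcoxon_signed_rank(tab_after$cov_pct,
                                            tab_foa$cov_pct))
    )
  }

  normative <- build_normative(profiles, targets = targets, method = method)
  ids <- cohort$subject_id %||% seq_len(n)
  cats_before <- sector_categories(
    tibble(subject_id = ids, profile = profiles), normative)
  cats_after <- sector_categories(
    tibble(subject_id = ids, profile = warped), normative)

  structure(
    list(sector_tables = dplyr::relocate(sector_tables, "condition"),
         cov_reduction = reduction, wilcoxon = wilcox,
         targets = targets, targets_foa = targets_foa,
         normative = normative, peaks = peaks,
         profiles = profiles, profiles_pn = warped,
         categories_before = cats_before, categories_after = cats_after,
         category_changes = count_category_changes(cats_before, cats_after),
         n = n),
    class = "rnflt_pn_analysis"
  )
}

# NA (rather than an error) for degenerate zero-variance sectors, so a
# flat cohort still yields a complete report
safe_cov_reduction <- function(before, after) {
  ifelse(before > 0, 100 * (before - after) / before, NA_real_)
}

cohort_profiles <- function(cohort, config) {
  if (!is.null(cohort$map)) {
    purrr::map(cohort$map, resample_circumpapillary,
               radius_mm = config$primary_radius_mm,
               step_deg = config$step_deg)
  } else if (!is.null(cohort$profile)) {
    cohort$profile
  } else {
    abort("`cohort` needs a `map` or `profile` list-column.")
  }
}

cohort_foa <- function(cohort) {
  if (!is.null(cohort$foa_deg)) return(cohort$foa_deg)
  if (!is.null(cohort$landmarks)) {
    return(purrr::map_dbl(cohort$landmarks, compute_foa))
  }
  abort("FOA alignment needs a `foa_deg` column or `landmarks` list-column.")
}

#' @export
print.rnflt_pn_analysis <- function(x, ...) {
  cat(sprintf("<rnflt_pn_analysis> n = %d subjects\n", x$n))
  cat(sprintf("  mean peak targets: ST %.2f deg, IT %.2f deg\n",
              x$targets$m_st_deg, x$targets$m_it_deg))
  red <- x$cov_reduction$reduction_pn_pct
  cat(sprintf("  mean CoV: %.2f%% -> %.2f%% (mean per-CH reduction %.2f%%)\n",
              mean(x$cov_reduction$cov_before),
              mean(x$cov_reduction$cov_after_pn), mean(red)))
  cat(sprintf("  largest reduction: CH%d (%.2f%%)\n",
              x$cov_reduction$ch[which.max(red)], max(red)))
  cat(sprintf("  Wilcoxon (12 paired CoVs, before vs after PN): p = %.4g\n",
              x$wilcoxon$p_value[1]))
  invisible(x)
}

#' Categorize one profile before and after peak normalization
#'
#' Detects the subject's peaks, warps the profile to the normative model's
#' mean peak locations, and labels each clock-hour sector both ways against
#' the model's sector-level lower limits.
#'
#' @param profile A profile tibble.
#' @param normative An `rnflt_normative` built with peak targets.
#' @param config An [analysis_config].
#' @return A tibble: `ch`, `value_before_um`, `label_before`,
#'   `value_after_um`, `label_after`; the detected peaks and warp targets
#'   are attached as attribute `warp`.
#' @export
classify_profile <- function(profile, normative, config = analysis_config()) {
  stopifnot(inherits(normative, "rnflt_normative"))
  if (is.na(normative$m_st_deg)) {
    abort("`normative` has no mean peak targets; rebuild with `targets =`.")
  }
  check_profile(profile)
  pk <- detect_peaks(profile, config)
  if (pk$degenerate) warn("degenerate peak window; labels may be unstable.")
  step <- profile_step(profile)
  m_st <- round(normative$m_st_deg / step) * step
  m_it <- round(normative$m_it_deg / step) * step
  p_st <- min(max(pk$st_angle_deg, step), 180 - step)
  p_it <- min(max(pk$it_angle_deg, 180 + step), 360 - step)
  warped <- warp_profile(profile, warp_spec(p_st, p_it, m_st, m_it))
  sm_b <- sector_means(profile, centered = normative$centered)
  sm_a <- sector_means(warped, centered = normative$centered)
  out <- tibble(
    ch = sm_b$ch,
    value_before_um = sm_b$value_um,
    label_before = classify_rnflt(sm_b$value_um,
                                  normative$sector$lower95_um,
                                  normative$sector$lower99_um),
    value_after_um = sm_a$value_um,
    label_after = classify_rnflt(sm_a$value_um,
                                 normative$sector$lower95_um,
                                 normative$sector$lower99_um)
  )
  attr(out, "warp") <- list(p_st = pk$st_angle_deg, p_it = pk$it_angle_deg,
                            m_st = m_st, m_it = m_it)
  out
}
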