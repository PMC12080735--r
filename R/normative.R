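#' Build a normative RNFLT model from a cohort of profiles
#'
#' Computes the per-angle and per-clock-hour sample mean and standard
#' deviation (n-1 denominator) across profiles, and the one-sided lower
#' normative limits used for categorization. With the default parametric
#' method the limits are `mean - 1.96 sd` (95% level) and `mean - 2.576 sd`
#' (99% level); only thin values are ever flagged, so the upper tail is
#' left open. With `method = "percentile"` the 2.5th and 0.5th empirical
#' percentiles are used instead.
#'
#' @param profiles List of profile tibbles (all on the same angular grid),
#'   or a cohort tibble with a `profile` list-column.
#' @param targets Optional one-row tibble with `m_st_deg`, `m_it_deg`: the
#'   mean peak locations stored with the model as warp targets.
#' @param method `"parametric"` (Gaussian limits, default) or
#'   `"percentile"`.
#' @param z95,z99 Gaussian multipliers (defaults 1.96 and 2.576).
#' @param foa_aligned Were the input profiles FOA-aligned? (bookkeeping)
#' @param centered Sector convention, see [clock_hour_of()].
#' @return An object of class `rnflt_normative` with elements `angle` and
#'   `sector` (tibbles with mean/sd/lower limits), `m_st_deg`, `m_it_deg`,
#'   `n`, `method`, `z95`, `z99`, `foa_aligned`.
#' @export
build_normative <- function(profiles, targets = NULL,
                            method = c("parametric", "percentile"),
                            z95 = 1.96, z99 = 2.576,
                            foa_aligned = FALSE, centered = TRUE) {
  method <- match.arg(method)
  profiles <- as_profile_list(profiles)
  n <- length(profiles)
  if (n < 2) abort("need at least 2 profiles for a normative model.")
  mat <- vapply(profiles, function(p) p$thickness_um,
                numeric(nrow(profiles[[1]])))
  angles <- profiles[[1]]$angle_deg
  lims <- function(m) {
    mu <- rowMeans(m)
    sdv <- apply(m, 1, sd)
    if (method == "parametric") {
      list(mean = mu, sd = sdv,
           lower95 = mu - z95 * sdv, lower99 = mu - z99 * sdv)
    } else {
      list(mean = mu, sd = sdv,
           lower95 = apply(m, 1, quantile, probs = 0.025, names = FALSE),
           lower99 = apply(m, 1, quantile, probs = 0.005, names = FALSE))
    }
  }
  la <- lims(mat)
  angle_tbl <- tibble(angle_deg = angles, mean_um = la$mean, sd_um = la$sd,
                      lower95_um = la$lower95, lower99_um = la$lower99)
  sect_mat <- vapply(profiles,
                     function(p) sector_means(p, centered = centered)$value_um,
                     numeric(12))
  ls <- lims(sect_mat)
  sector_tbl <- tibble(ch = 1:12, mean_um = ls$mean, sd_um = ls$sd,
                       lower95_um = ls$lower95, lower99_um = ls$lower99,
                       cov_pct = 100 * ls$sd / ls$mean)
  structure(
    list(angle = angle_tbl, sector = sector_tbl,
         m_st_deg = targets$m_st_deg %||% NA_real_,
         m_it_deg = targets$m_it_deg %||% NA_real_,
         n = n, method = method, z95 = z95, z99 = z99,
         foa_aligned = foa_aligned, centered = centered),
    class = "rnflt_normative"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_profile_list <- function(profiles) {
  if (is.data.frame(profiles)) {
    if (is.null(profiles$profile)) {
      abort("a cohort tibble needs a `profile` list-column.")
    }
    profiles <- profiles$profile
  }
  if (!is.list(profiles) || length(profiles) == 0) {
    abort("`profiles` must be a non-empty list of profile tibbles.")
  }
  purrr::walk(profiles, check_profile)
  profiles
}

#' @export
print.rnflt_normative <- function(x, ...) {
  cat(sprintf(
    "<rnflt_normative> n = %d profiles, %s limits%s\n", x$n, x$method,
    if (x$foa_aligned) ", FOA-aligned" else ""
  ))
  if (!is.na(x$m_st_deg)) {
    cat(sprintf("  mean peak targets: ST %.2f deg, IT %.2f deg\n",
                x$m_st_deg, x$m_it_deg))
  }
  print(x$sector, n = 12)
  invisible(x)
}

#' Categorize thickness values against normative lower limits
#'
#' A value at or above the 95% lower limit is `normal`; between the 99% and
#' 95% limits, `borderline`; below the 99% limit, `abnormal`. Only thin
#' values are flagged.
#'
#' @param value_um Thickness value(s), micrometres.
#' @param lower95_um,lower99_um Lower limits (same length or length 1).
#' @return A factor with levels `normal`, `borderline`, `abnormal`.
#' @examples
#' classify_rnflt(c(100, 60, 40), lower95_um = 70, lower99_um = 50)
#' @export
classify_rnflt <- function(value_um, lower95_um, lower99_um) {
  if (any(lower99_um > lower95_um)) {
    abort("`lower99_um` must not exceed `lower95_um`.")
  }
  lab <- ifelse(value_um >= lower95_um, "normal",
                ifelse(value_um >= lower99_um, "borderline", "abnormal"))
  factor(lab, levels = c("normal", "borderline", "abnormal"))
}

#' Clock-hour summary table of a cohort
#'
#' For each clock hour, the cohort mean and standard deviation of the
#' per-subject sector means, and the coefficient of variation
#' `100 * sd / mean` (percent).
#'
#' @inheritParams build_normative
#' @return A tibble with `ch`, `mean_um`, `sd_um`, `cov_pct`.
#' @export
sector_table <- function(profiles, centered = TRUE) {
  profiles <- as_profile_list(profiles)
  if (length(profiles) < 2) abort("need at least 2 profiles.")
  m <- vapply(profiles,
              function(p) sector_means(p, centered = centered)$value_um,
              numeric(12))
  mu <- rowMeans(m)
  sdv <- apply(m, 1, sd)
  cov <- ifelse(mu > 0, 100 * sdv / mu, NA_real_)
  if (any(mu <= 0)) warn("zero sector mean: CoV undefined for that sector.")
  tibble(ch = 1:12, mean_um = mu, sd_um = sdv, cov_pct = cov)
}

#' Relative reduction of a coefficient of variation
#'
#' `100 * (cov_before - cov_after) / cov_before`, in percent; positive when
#' variability decreased.
#'
#' @param cov_before,cov_after CoV values in percent; `cov_before` must be
#'   positive.
#' @return Percent reduction (vectorized).
#' @examples
#' cov_reduction(18.40, 16.49)
#' @export
cov_reduction <- function(cov_before, cov_after) {
  if (any(cov_before <= 0)) abort("`cov_before` must be positive.")
  100 * (cov_before - cov_after) / cov_before
}

#' Per-subject clock-hour categorization
#'
#' Labels every subject's sector means against a normative model's
#' sector-level lower limits.
#'
#' @param profiles List of profiles or cohort tibble (see
#'   [build_normative()]).
#' @param normative An `rnflt_normative` model.
#' @return A tibble: `subject_id`, `ch`, `value_um`, `label`.
#' @export
sector_categories <- function(profiles, normative) {
  stopifnot(inherits(normative, "rnflt_normative"))
  ids <- if (is.data.frame(profiles) && !is.null(profiles$subject_id)) {
    profiles$subject_id
  } else NULL
  profiles <- as_profile_list(profiles)
  ids <- ids %||% seq_along(profiles)
  purrr::map2_dfr(profiles, ids, function(p, id) {
    sm <- sector_means(p, centered = normative$centered)
    tibble(
      subject_id = id, ch = sm$ch, value_um = sm$value_um,
      label = classify_rnflt(sm$value_um,
                             normative$sector$lower95_um,
                             normative$sector$lower99_um)
    )
  })
}

#' Summarize categorization changes between two label tables
#'
#' @param labels_before,labels_after Congruent tibbles from
#'   [sector_categories()] (same subjects and clock hours, same order).
#' @return A list: `n_subjects_changed` (subjects with at least one changed
#'   sector), `n_sectors_changed`, and `transitions`, a tibble counting each
#'   from -> to label pair.
#' @export
count_category_changes <- function(labels_before, labels_after) {
  need <- c("subject_id", "ch", "label")
  if (!all(need %in% names(labels_before)) ||
      !all(need %in% names(labels_after)) ||
      nrow(labels_before) != nrow(labels_after) ||
      !identical(labels_before$subject_id, labels_after$subject_id) ||
      !identical(labels_before$ch, labels_after$ch)) {
    abort("label tables must cover identical subject/clock-hour pairs.")
  }
  changed <- labels_before$label != labels_after$label
  transitions <- tibble(
    from = labels_before$label[changed],
    to = labels_after$label[changed]
  ) |>
    dplyr::count(.data$from, .data$to, name = "n")
  list(
    n_subjects_changed =
      length(unique(labels_before$subject_id[changed])),
    n_sectors_changed = sum(changed),
    transitions = transitions
  )
}
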