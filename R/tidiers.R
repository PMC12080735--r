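#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a normative model
#'
#' @param x An `rnflt_normative`.
#' @param type `"sector"` (default) for the clock-hour table or `"angle"`
#'   for the per-angle table.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.rnflt_normative <- function(x, type = c("sector", "angle"), ...) {
  type <- match.arg(type)
  if (type == "sector") x$sector else x$angle
}

#' One-row summary of a normative model
#'
#' @param x An `rnflt_normative`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.rnflt_normative <- function(x, ...) {
  tibble(
    n = x$n, method = x$method, foa_aligned = x$foa_aligned,
    m_st_deg = x$m_st_deg, m_it_deg = x$m_it_deg,
    mean_cov_pct = mean(x$sector$cov_pct)
  )
}

#' Tidy a peak-normalization analysis
#'
#' @param x An `rnflt_pn_analysis`.
#' @param type `"cov"` (default) for the per-clock-hour CoV and reduction
#'   table, `"sectors"` for the long condition-wise sector table,
#'   `"wilcoxon"` for the paired tests, or `"peaks"` for per-subject peaks.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.rnflt_pn_analysis <- function(x, type = c("cov", "sectors",
                                               "wilcoxon", "peaks"), ...) {
  type <- match.arg(type)
  switch(type,
    cov = x$cov_reduction,
    sectors = x$sector_tables,
    wilcoxon = x$wilcoxon,
    peaks = x$peaks
  )
}

#' One-row summary of a peak-normalization analysis
#'
#' @param x An `rnflt_pn_analysis`.
#' @param ... Unused.
#' @return A one-row tibble with cohort size, peak targets, mean CoV before
#'   and after normalization, the mean per-clock-hour CoV reduction, and
#'   the paired Wilcoxon p-value.
#' @export
glance.rnflt_pn_analysis <- function(x, ...) {
  tibble(
    n = x$n,
    m_st_deg = x$targets$m_st_deg, m_it_deg = x$targets$m_it_deg,
    mean_cov_before_pct = mean(x$cov_reduction$cov_before),
    mean_cov_after_pn_pct = mean(x$cov_reduction$cov_after_pn),
    mean_cov_reduction_pct = mean(x$cov_reduction$reduction_pn_pct),
    wilcoxon_p = x$wilcoxon$p_value[1],
    n_subjects_recategorized = x$category_changes$n_subjects_changed
  )
}
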