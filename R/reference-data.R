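#' Published clock-hour normative summary table
#'
#' A clock-hour summary (mean thickness, SD, and coefficient of variation,
#' before peak normalization, after peak normalization, and after peak
#' normalization with fovea-ONH-axis alignment) reported for a published
#' normative OCT cohort of 78 healthy eyes. Shipped as a worked-example
#' input for the CoV arithmetic ([cov_reduction()], `100 * sd / mean`); the
#' underlying per-subject data are not public, so these summary cells are
#' the only cohort-level reference values available.
#'
#' @return A tibble with columns `ch`, `mean_before_um`, `sd_before_um`,
#'   `cov_before_pct`, `mean_pn_um`, `sd_pn_um`, `cov_pn_pct`,
#'   `mean_pn_foa_um`, `sd_pn_foa_um`, `cov_pn_foa_pct`.
#' @examples
#' ref <- reference_sector_stats()
#' with(ref, 100 * sd_before_um / mean_before_um) # matches cov_before_pct
#' @export
reference_sector_stats <- function() {
  readr::read_csv(
    system.file("extdata", "reference_sector_stats.csv",
                package = "rnfltnorm", mustWork = TRUE),
    show_col_types = FALSE
  )
}
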