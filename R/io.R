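#' Write a cohort to disk as plain-text files
#'
#' Lays out one directory per run: `config.json`, `truth.csv`
#' (`subject_id`, `true_st_peak`, `true_it_peak`, `foa_deg`), and per
#' subject `<id>_map.csv` (headerless numeric grid), `<id>_landmarks.json`
#' (`{"fovea": [x, y], "onh": [x, y]}`) and `<id>_profile.csv`
#' (`angle_deg`, `thickness_um`).
#'
#' @param cohort A cohort tibble from [generate_cohort()].
#' @param dir Output directory (created if missing).
#' @param config Optional [cohort_config] to record alongside.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, config = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(config)) {
    jsonlite::write_json(unclass(config), file.path(dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  truth <- dplyr::select(cohort, "subject_id", "true_st_peak",
                         "true_it_peak", "foa_deg")
  readr::write_csv(truth, file.path(dir, "truth.csv"))
  purrr::pwalk(
    list(cohort$subject_id, cohort$map, cohort$landmarks, cohort$profile),
    function(id, map, lm, prof) {
      readr::write_csv(
        as.data.frame(map$grid), file.path(dir, paste0(id, "_map.csv")),
        col_names = FALSE
      )
      jsonlite::write_json(
        list(fovea = lm$fovea_xy, onh = lm$onh_xy,
             px_per_mm = map$px_per_mm, onh_center = map$onh_center,
             laterality = map$laterality),
        file.path(dir, paste0(id, "_landmarks.json")),
        auto_unbox = FALSE, digits = NA
      )
      readr::write_csv(prof, file.path(dir, paste0(id, "_profile.csv")))
    }
  )
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing `truth.csv` and per-subject files.
#' @return A cohort tibble with `subject_id`, truth columns, `map`,
#'   `landmarks` and `profile` list-columns.
#' @export
read_cohort <- function(dir) {
  truth <- readr::read_csv(file.path(dir, "truth.csv"),
                           show_col_types = FALSE)
  rows <- purrr::map(truth$subject_id, function(id) {
    meta <- jsonlite::read_json(
      file.path(dir, paste0(id, "_landmarks.json")), simplifyVector = TRUE
    )
    map <- read_rnflt_map(
      file.path(dir, paste0(id, "_map.csv")),
      px_per_mm = meta$px_per_mm, onh_center = meta$onh_center,
      laterality = meta$laterality
    )
    prof <- readr::read_csv(file.path(dir, paste0(id, "_profile.csv")),
                            show_col_types = FALSE)
    step <- 360 / nrow(prof)
    prof <- new_profile(prof$thickness_um, step_deg = step)
    list(map = map, landmarks = foa_landmarks(meta$fovea, meta$onh),
         profile = prof)
  })
  truth$map <- purrr::map(rows, "map")
  truth$landmarks <- purrr::map(rows, "landmarks")
  truth$profile <- purrr::map(rows, "profile")
  truth
}

#' Read an RNFLT map from a headerless CSV grid
#'
#' @param path CSV file, one row per image row, values in micrometres.
#' @inheritParams rnflt_map
#' @return An [rnflt_map].
#' @export
read_rnflt_map <- function(path, px_per_mm = 200 / 6,
                           onh_center = c(100, 100),
                           laterality = "right") {
  g <- as.matrix(readr::read_csv(path, col_names = FALSE,
                                 show_col_types = FALSE))
  dimnames(g) <- NULL
  rnflt_map(g, px_per_mm = px_per_mm, onh_center = onh_center,
            laterality = laterality)
}

#' Write a TSNIT profile as CSV
#'
#' @param profile A profile tibble (`angle_deg`, `thickness_um`).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  check_profile(profile)
  readr::write_csv(profile[, c("angle_deg", "thickness_um")], path)
  invisible(path)
}

#' Read a TSNIT profile from CSV
#'
#' @param path CSV with columns `angle_deg`, `thickness_um`.
#' @return A profile tibble.
#' @export
read_profile <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  check_profile(d)
  new_profile(d$thickness_um[order(d$angle_deg)],
              step_deg = 360 / nrow(d))
}

#' Write a normative model to JSON (+ per-angle CSV)
#'
#' @param normative An `rnflt_normative`.
#' @param path JSON output path; a sibling `<path>_angle.csv` carries the
#'   per-angle table.
#' @return `path`, invisibly.
#' @export
write_normative <- function(normative, path) {
  stopifnot(inherits(normative, "rnflt_normative"))
  jsonlite::write_json(
    list(n = normative$n, method = normative$method,
         z95 = normative$z95, z99 = normative$z99,
         m_st_deg = normative$m_st_deg, m_it_deg = normative$m_it_deg,
         foa_aligned = normative$foa_aligned, centered = normative$centered,
         sector = normative$sector),
    path, auto_unbox = TRUE, digits = NA, dataframe = "columns"
  )
  readr::write_csv(normative$angle,
                   paste0(sub("\\.json$", "", path), "_angle.csv"))
  invisible(path)
}

#' Read a normative model written by [write_normative()]
#'
#' @param path JSON path.
#' @return An `rnflt_normative`.
#' @export
read_normative <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  angle <- readr::read_csv(paste0(sub("\\.json$", "", path), "_angle.csv"),
                           show_col_types = FALSE)
  structure(
    list(angle = as_tibble(angle), sector = as_tibble(j$sector),
         m_st_deg = j$m_st_deg, m_it_deg = j$m_it_deg, n = j$n,
         method = j$method, z95 = j$z95, z99 = j$z99,
         foa_aligned = j$foa_aligned, centered = j$centered),
    class = "rnflt_normative"
  )
}
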