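#' Clock-hour sector of a TSNIT angle
#'
#' Maps TSNIT angles to the twelve 30-degree clock-hour (CH) sectors of a
#' right-eye circumpapillary circle. By default each sector is centred on
#' its hour meridian: CH9 (temporal) on 0 deg, CH12 (superior) on 90, CH3
#' (nasal) on 180, CH6 (inferior) on 270, so CH9 spans [345, 360) U [0, 15).
#' With `centered = FALSE` sectors instead start at their meridian (CH9 =
#' [0, 30)).
#'
#' @param angle_deg Angles in degrees (any real; reduced mod 360).
#' @param centered Centre sectors on hour meridians (default TRUE).
#' @return Integer clock hours in 1..12.
#' @examples
#' clock_hour_of(c(0, 90, 180, 270, 359))
#' @export
clock_hour_of <- function(angle_deg, centered = TRUE) {
  a <- angle_deg %% 360
  k <- if (centered) floor((a + 15) / 30) %% 12 else floor(a / 30) %% 12
  as.integer(((9 + k - 1) %% 12) + 1)
}

#' Clock-hour meridian centres
#'
#' @return A tibble with `ch` (1..12) and `center_deg`, the TSNIT angle of
#'   each hour meridian (CH9 = 0).
#' @export
clock_hour_centers <- function() {
  k <- 0:11
  tibble(ch = as.integer(((9 + k - 1) %% 12) + 1), center_deg = k * 30)
}

#' Mean thickness within one clock-hour sector
#'
#' @param profile A profile tibble (`angle_deg`, `thickness_um`).
#' @param ch Clock hour, integer 1..12.
#' @param centered Sector convention, see [clock_hour_of()].
#' @return Mean thickness (micrometres) over the sector's samples.
#' @export
sector_mean <- function(profile, ch, centered = TRUE) {
  check_profile(profile)
  if (!ch %in% 1:12) abort("`ch` must be an integer in 1..12.")
  sel <- clock_hour_of(profile$angle_deg, centered = centered) == ch
  mean(profile$thickness_um[sel])
}

#' Per-subject clock-hour sector means
#'
#' @param profile A profile tibble.
#' @param centered Sector convention, see [clock_hour_of()].
#' @return A tibble with `ch` (1..12) and `value_um`.
#' @export
sector_means <- function(profile, centered = TRUE) {
  check_profile(profile)
  ch <- clock_hour_of(profile$angle_deg, centered = centered)
  out <- tibble(ch = ch, thickness_um = profile$thickness_um) |>
    dplyr::group_by(.data$ch) |>
    dplyr::summarise(value_um = mean(.data$thickness_um), .groups = "drop") |>
    dplyr::arrange(.data$ch)
  out
}
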