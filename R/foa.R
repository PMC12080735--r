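#' Fovea-ONH landmark pair
#'
#' @param fovea_xy,onh_xy Length-2 numeric `c(x, y)` pixel coordinates
#'   (image x rightward, image y downward) of the foveal centre and ONH
#'   centre marked on the en-face (SLO) image.
#' @return A list of class `foa_landmarks`.
#' @export
foa_landmarks <- function(fovea_xy, onh_xy) {
  fovea_xy <- as.numeric(fovea_xy); onh_xy <- as.numeric(onh_xy)
  if (length(fovea_xy) != 2 || length(onh_xy) != 2 ||
      anyNA(c(fovea_xy, onh_xy))) {
    abort("landmarks must be numeric c(x, y) pairs.")
  }
  if (all(fovea_xy == onh_xy)) abort("fovea and ONH centres coincide.")
  structure(list(fovea_xy = fovea_xy, onh_xy = onh_xy),
            class = "foa_landmarks")
}

#' Angle of the fovea-ONH axis to the horizontal image axis
#'
#' Returns the signed elevation, in degrees, of the fovea relative to the
#' ONH, measured against the horizontal image axis in a y-up frame: a fovea
#' inferior to the ONH gives a negative angle (cohorts typically average
#' about -10 deg). The horizontal displacement enters as a magnitude, so the
#' sign does not depend on which side of the ONH the fovea lies
#' (i.e. it is laterality-invariant).
#'
#' @param landmarks A [foa_landmarks] object (or list with `fovea_xy`,
#'   `onh_xy`).
#' @return The FOA angle in degrees, in (-90, 90).
#' @examples
#' compute_foa(foa_landmarks(c(40, 120), c(100, 100)))
#' @export
compute_foa <- function(landmarks) {
  f <- landmarks$fovea_xy; o <- landmarks$onh_xy
  if (is.null(f) || is.null(o)) abort("need `fovea_xy` and `onh_xy`.")
  if (all(f == o)) abort("fovea and ONH centres coincide.")
  dx <- abs(f[1] - o[1])
  if (dx == 0) abort("fovea-ONH axis is vertical; FOA undefined in (-90, 90).")
  # image y grows downward; flip to y-up so "fovea below" is negative
  atan2(o[2] - f[2], dx) * 180 / pi
}

#' Rotationally align a profile's fovea-ONH axis with the horizontal
#'
#' Applies the circular shift of the TSNIT profile equivalent to rotating
#' the en-face image about the ONH centre until the fovea-ONH axis (FOA)
#' lies on the horizontal image axis. A feature at TSNIT angle `theta`
#' moves to `theta - foa_deg`; values at non-grid angles are obtained by
#' circular linear interpolation.
#'
#' @param profile A profile tibble (`angle_deg`, `thickness_um`).
#' @param foa_deg FOA angle in degrees, `abs(foa_deg) < 90`.
#' @return The rotationally corrected profile tibble.
#' @export
align_foa <- function(profile, foa_deg) {
  check_profile(profile)
  if (!is.numeric(foa_deg) || length(foa_deg) != 1 || abs(foa_deg) >= 90) {
    abort("`foa_deg` must be a single angle with |foa| < 90.")
  }
  step <- profile_step(profile)
  out <- profile
  out$thickness_um <- interp_profile(profile$thickness_um, step,
                                     profile$angle_deg + foa_deg)
  out
}

#' Rotate landmark coordinates about the ONH centre
#'
#' Rotates the fovea about the ONH by `delta_deg` (positive =
#' counter-clockwise in the y-up frame, i.e. the rotation that [align_foa]
#' applies when `delta_deg = foa_deg`). Rotating by the FOA angle itself
#' brings the axis onto the horizontal: `compute_foa()` of the result is 0.
#'
#' @param landmarks A [foa_landmarks].
#' @param delta_deg Rotation in degrees.
#' @return Rotated [foa_landmarks].
#' @export
rotate_landmarks <- function(landmarks, delta_deg) {
  o <- landmarks$onh_xy
  d <- landmarks$fovea_xy - o
  th <- delta_deg * pi / 180
  # CCW in y-up == CW in image (y-down) coordinates
  dx <- d[1] * cos(th) + d[2] * sin(th)
  dy <- -d[1] * sin(th) + d[2] * cos(th)
  foa_landmarks(o + c(dx, dy), o)
}
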