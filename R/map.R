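#' ONH-centered RNFL thickness map
#'
#' Constructs the 2D retinal nerve fiber layer thickness (RNFLT) map object
#' used throughout the package. The grid is an en-face thickness raster (in
#' micrometres) centred on the optic nerve head (ONH); `grid[y, x]` holds the
#' thickness at image column `x` and row `y` (1-based), with image x running
#' rightward and image y running downward, as in raster images.
#'
#' @param grid Numeric matrix of thickness values in micrometres. All values
#'   must be finite and non-negative. The conventional size is 200 x 200
#'   (a 6 x 6 mm en-face cube face), but any square grid is accepted.
#' @param px_per_mm Pixel pitch, pixels per millimetre. Default `200/6`
#'   (200 pixels spanning 6 mm).
#' @param onh_center Length-2 numeric `c(x, y)` pixel coordinates (1-based)
#'   of the ONH centre.
#' @param laterality `"right"` or `"left"`.
#' @return An object of class `rnflt_map`.
#' @examples
#' m <- rnflt_map(matrix(100, 200, 200))
#' m
#' @export
rnflt_map <- function(grid, px_per_mm = 200 / 6,
                      onh_center = c(100, 100),
                      laterality = c("right", "left")) {
  laterality <- match.arg(laterality)
  if (!is.matrix(grid) || !is.numeric(grid)) {
    abort("`grid` must be a numeric matrix.")
  }
  if (anyNA(grid) || any(!is.finite(grid))) {
    abort("`grid` must be finite everywhere.")
  }
  if (any(grid < 0)) abort("thickness values must be non-negative.")
  if (!is.numeric(px_per_mm) || length(px_per_mm) != 1 || px_per_mm <= 0) {
    abort("`px_per_mm` must be a single positive number.")
  }
  onh_center <- as.numeric(onh_center)
  if (length(onh_center) != 2 || anyNA(onh_center)) {
    abort("`onh_center` must be numeric c(x, y).")
  }
  if (onh_center[1] < 1 || onh_center[1] > ncol(grid) ||
      onh_center[2] < 1 || onh_center[2] > nrow(grid)) {
    abort("`onh_center` must lie inside the grid.")
  }
  structure(
    list(grid = grid, px_per_mm = px_per_mm,
         onh_center = onh_center, laterality = laterality),
    class = "rnflt_map"
  )
}

#' @export
print.rnflt_map <- function(x, ...) {
  cat(sprintf(
    "<rnflt_map> %d x %d px (%.2f px/mm), ONH at (%.1f, %.1f), %s eye\n",
    nrow(x$grid), ncol(x$grid), x$px_per_mm,
    x$onh_center[1], x$onh_center[2], x$laterality
  ))
  cat(sprintf("  thickness range: %.1f - %.1f um\n",
              min(x$grid), max(x$grid)))
  invisible(x)
}

#' Translate a map so the ONH centre sits at a target pixel
#'
#' Applies the integer pixel translation that brings the stored ONH centre to
#' `target` (default `(100, 100)`, the conventional image centre). Sub-pixel
#' centres are rounded; no resampling takes place. Pixels exposed by the
#' shift are filled with `fill`.
#'
#' @param map An [rnflt_map].
#' @param target Length-2 `c(x, y)` target pixel for the ONH centre.
#' @param fill Fill value for exposed pixels (default 0).
#' @return The translated [rnflt_map] with `onh_center = target`.
#' @export
recenter_map <- function(map, target = c(100, 100), fill = 0) {
  stopifnot(inherits(map, "rnflt_map"))
  dx <- round(target[1] - map$onh_center[1])
  dy <- round(target[2] - map$onh_center[2])
  g <- map$grid
  nr <- nrow(g); nc <- ncol(g)
  if (abs(dx) >= nc / 2 || abs(dy) >= nr / 2) {
    abort("recentering would push more than half the grid out of frame.")
  }
  out <- matrix(fill, nr, nc)
  # destination index ranges for a shift of (+dx, +dy)
  src_x <- max(1, 1 - dx):min(nc, nc - dx)
  src_y <- max(1, 1 - dy):min(nr, nr - dy)
  out[src_y + dy, src_x + dx] <- g[src_y, src_x]
  map$grid <- out
  map$onh_center <- map$onh_center + c(dx, dy)
  map
}

#' Mirror a left-eye map into right-eye orientation
#'
#' Left-eye maps are mirrored about the vertical axis through the ONH column
#' so that temporal retina lies at image-left for every map, matching the
#' right-eye TSNIT convention. Right-eye maps are returned unchanged. Pixels
#' whose mirror source falls outside the grid are filled with `fill`.
#'
#' @inheritParams recenter_map
#' @param fill Fill value for columns without a mirror source.
#' @return An [rnflt_map] with `laterality = "right"`.
#' @export
flip_to_right_eye <- function(map, fill = 0) {
  stopifnot(inherits(map, "rnflt_map"))
  if (map$laterality == "right") return(map)
  map$grid <- mirror_about_column(map$grid, map$onh_center[1], fill)
  map$laterality <- "right"
  map
}

# x -> 2*cx - x column reflection; sources outside the grid give `fill`.
mirror_about_column <- function(grid, cx, fill = 0) {
  nc <- ncol(grid)
  src <- round(2 * cx - seq_len(nc))
  ok <- src >= 1 & src <= nc
  out <- matrix(fill, nrow(grid), nc)
  out[, ok] <- grid[, src[ok]]
  out
}

# Bilinear interpolation of `grid` at continuous 1-based (x, y) positions.
bilinear_at <- function(grid, x, y) {
  nr <- nrow(grid); nc <- ncol(grid)
  x0 <- pmin(pmax(floor(x), 1), nc - 1)
  y0 <- pmin(pmax(floor(y), 1), nr - 1)
  fx <- x - x0
  fy <- y - y0
  i00 <- cbind(y0, x0)
  v00 <- grid[i00]
  v01 <- grid[cbind(y0, x0 + 1)]
  v10 <- grid[cbind(y0 + 1, x0)]
  v11 <- grid[cbind(y0 + 1, x0 + 1)]
  v00 * (1 - fx) * (1 - fy) + v01 * fx * (1 - fy) +
    v10 * (1 - fx) * fy + v11 * fx * fy
}

# Nearest-neighbour variant, kept for oracle comparisons.
nearest_at <- function(grid, x, y) {
  grid[cbind(pmin(pmax(round(y), 1), nrow(grid)),
             pmin(pmax(round(x), 1), ncol(grid)))]
}

#' Pixel displacement of a TSNIT angle
#'
#' The TSNIT convention places 0 deg at the 9 o'clock (temporal, image-left)
#' position of a right-eye image and increases toward the image top
#' (temporal, superior, nasal, inferior): 90 deg is superior, 180 nasal,
#' 270 inferior. In image coordinates (x rightward, y downward) the unit
#' displacement for angle `theta` is `(-cos(theta), -sin(theta))`.
#'
#' @param theta_deg Angles in degrees.
#' @return A two-column matrix of unit (dx, dy) image displacements.
#' @keywords internal
tsnit_direction <- function(theta_deg) {
  th <- theta_deg * pi / 180
  cbind(dx = -cos(th), dy = -sin(th))
}

#' Resample a circumpapillary TSNIT profile from a thickness map
#'
#' Samples the map by bilinear interpolation along a circle of radius
#' `radius_mm` centred on the stored ONH centre, every `step_deg` degrees, in
#' TSNIT order (0 deg = temporal / 9 o'clock for a right eye).
#'
#' @param map An [rnflt_map], normally recentered and in right-eye
#'   orientation.
#' @param radius_mm Circle radius in millimetres (default 1.7; the
#'   profile is also commonly read at 1.3, 1.5, 1.9 and 2.1 mm).
#' @param step_deg Angular sampling step in degrees (default 0.5, giving 720
#'   samples).
#' @param method `"bilinear"` (default) or `"nearest"`.
#' @return A tibble with columns `angle_deg` and `thickness_um` and
#'   attributes `radius_mm` and `step_deg`.
#' @examples
#' m <- rnflt_map(matrix(100, 200, 200))
#' p <- resample_circumpapillary(m, radius_mm = 1.7)
#' range(p$thickness_um)
#' @export
resample_circumpapillary <- function(map, radius_mm = 1.7, step_deg = 0.5,
                                     method = c("bilinear", "nearest")) {
  stopifnot(inherits(map, "rnflt_map"))
  method <- match.arg(method)
  if (radius_mm <= 0) abort("`radius_mm` must be positive.")
  r_px <- radius_mm * map$px_per_mm
  cx <- map$onh_center[1]; cy <- map$onh_center[2]
  angles <- seq(0, 360 - step_deg, by = step_deg)
  d <- tsnit_direction(angles)
  x <- cx + r_px * d[, "dx"]
  y <- cy + r_px * d[, "dy"]
  if (any(x < 1 | x > ncol(map$grid) | y < 1 | y > nrow(map$grid))) {
    abort("sampling circle leaves the thickness grid.")
  }
  v <- switch(method,
    bilinear = bilinear_at(map$grid, x, y),
    nearest = nearest_at(map$grid, x, y)
  )
  new_profile(v, step_deg = step_deg, radius_mm = radius_mm)
}

new_profile <- function(thickness_um, step_deg = 0.5, radius_mm = NA_real_) {
  angles <- seq(0, 360 - step_deg, by = step_deg)
  stopifnot(length(thickness_um) == length(angles))
  out <- tibble(angle_deg = angles, thickness_um = as.numeric(thickness_um))
  attr(out, "step_deg") <- step_deg
  attr(out, "radius_mm") <- radius_mm
  out
}

profile_step <- function(profile) {
  s <- attr(profile, "step_deg")
  if (!is.null(s)) return(s)
  360 / nrow(profile)
}

check_profile <- function(profile) {
  if (!is.data.frame(profile) ||
      !all(c("angle_deg", "thickness_um") %in% names(profile))) {
    abort("a profile must have columns `angle_deg` and `thickness_um`.")
  }
  invisible(profile)
}

# Circular linear interpolation of a regularly sampled profile at arbitrary
# angles (degrees). Wraps across the 0/360 seam.
interp_profile <- function(thickness, step_deg, at_deg) {
  n <- length(thickness)
  pos <- (at_deg %% 360) / step_deg
  i0 <- floor(pos)
  f <- pos - i0
  v0 <- thickness[(i0 %% n) + 1]
  v1 <- thickness[((i0 + 1) %% n) + 1]
  v0 * (1 - f) + v1 * f
}
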