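#' Binary retinal-vessel mask
#'
#' @param grid Binary (0/1) matrix, same raster convention as [rnflt_map].
#' @param onh_center `c(x, y)` pixel coordinates of the ONH centre.
#' @param px_per_mm Pixel pitch.
#' @return An object of class `vessel_mask`.
#' @export
vessel_mask <- function(grid, onh_center = c(100, 100),
                        px_per_mm = 200 / 6) {
  if (!is.matrix(grid) || !all(grid %in% c(0, 1))) {
    abort("`grid` must be a binary (0/1) matrix.")
  }
  structure(list(grid = matrix(as.integer(grid), nrow(grid), ncol(grid)),
                 onh_center = as.numeric(onh_center),
                 px_per_mm = px_per_mm),
            class = "vessel_mask")
}

#' @export
print.vessel_mask <- function(x, ...) {
  cat(sprintf("<vessel_mask> %d x %d px, %d vessel pixels\n",
              nrow(x$grid), ncol(x$grid), sum(x$grid)))
  invisible(x)
}

#' Retain only thick vessels in a binary mask
#'
#' Removes connected structures whose local width does not exceed
#' `min_width_px`: the mask is opened with a disc of radius
#' `ceiling(min_width_px / 2)` and every connected component of the
#' original mask that still has surviving pixels is reconstructed in full;
#' components erased by the opening (nowhere wider than the disc) are
#' dropped.
#'
#' @param mask A [vessel_mask].
#' @param min_width_px Width threshold in pixels (default 4: vessels wider
#'   than 4 px are kept).
#' @return The filtered [vessel_mask].
#' @export
retain_thick_vessels <- function(mask, min_width_px = 4) {
  stopifnot(inherits(mask, "vessel_mask"))
  g <- mask$grid
  if (sum(g) == 0) return(mask)
  brush <- EBImage::makeBrush(2 * ceiling(min_width_px / 2) + 1, "disc")
  opened <- EBImage::opening(g, brush)
  labels <- EBImage::bwlabel(g)
  keep <- sort(unique(labels[opened > 0 & labels > 0]))
  mask$grid <- matrix(as.integer(labels %in% keep), nrow(g), ncol(g))
  mask
}

#' Skeletonize a binary vessel mask
#'
#' Topology-preserving thinning to a one-pixel-wide centerline
#' (Zhang-Suen two-subiteration thinning).
#'
#' @param mask A [vessel_mask].
#' @return The skeletonized [vessel_mask].
#' @export
skeletonize_mask <- function(mask) {
  stopifnot(inherits(mask, "vessel_mask"))
  mask$grid <- zhang_suen(mask$grid)
  mask
}

# Zhang-Suen thinning on a 0/1 matrix, vectorized over candidate pixels.
zhang_suen <- function(g) {
  g <- g != 0
  nr <- nrow(g); nc <- ncol(g)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- g
  shift <- function(m, dy, dx) {
    m[(2 + dy):(nr + 1 + dy), (2 + dx):(nc + 1 + dx)]
  }
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      core <- pad[2:(nr + 1), 2:(nc + 1)]
      # neighbours P2..P9 clockwise from north
      p2 <- shift(pad, -1, 0); p3 <- shift(pad, -1, 1)
      p4 <- shift(pad, 0, 1); p5 <- shift(pad, 1, 1)
      p6 <- shift(pad, 1, 0); p7 <- shift(pad, 1, -1)
      p8 <- shift(pad, 0, -1); p9 <- shift(pad, -1, -1)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      seqn <- list(p2, p3, p4, p5, p6, p7, p8, p9, p2)
      a <- 0
      for (i in 1:8) a <- a + (!seqn[[i]] & seqn[[i + 1]])
      if (step == 1) {
        cond <- core & b >= 2 & b <= 6 & a == 1 &
          !(p2 & p4 & p6) & !(p4 & p6 & p8)
      } else {
        cond <- core & b >= 2 & b <= 6 & a == 1 &
          !(p2 & p4 & p8) & !(p2 & p6 & p8)
      }
      if (any(cond)) {
        changed <- TRUE
        core[cond] <- FALSE
        pad[2:(nr + 1), 2:(nc + 1)] <- core
      }
    }
    if (!changed) break
  }
  matrix(as.integer(pad[2:(nr + 1), 2:(nc + 1)]), nr, nc)
}

#' Mean angular vessel location within a TSNIT window
#'
#' Collects skeleton pixels whose radial distance from the ONH centre lies
#' within `annulus_halfwidth_px` of the scan radius and whose TSNIT angle
#' falls in `window` (bounds inclusive), and returns the arithmetic mean of
#' their angles. For a window ending at 360 deg, pixels at 0 deg are read
#' as 360 so the mean is not dragged across the seam.
#'
#' @param mask A (skeletonized) [vessel_mask].
#' @param radius_mm Scan radius (default 1.7 mm).
#' @param window Angular window `c(lo, hi)` in degrees, e.g. `c(0, 110)`
#'   (ST) or `c(250, 360)` (IT).
#' @param annulus_halfwidth_px Annulus half-width in pixels (default 1; a
#'   zero-width circle would miss most raster pixels).
#' @return Mean TSNIT angle in degrees.
#' @export
mean_vessel_angle <- function(mask, radius_mm = 1.7, window = c(0, 110),
                              annulus_halfwidth_px = 1) {
  stopifnot(inherits(mask, "vessel_mask"))
  idx <- which(mask$grid == 1, arr.ind = TRUE)
  if (nrow(idx) == 0) abort("no vessel pixels.")
  dx <- idx[, "col"] - mask$onh_center[1]
  dy <- idx[, "row"] - mask$onh_center[2]
  r <- sqrt(dx^2 + dy^2)
  r_target <- radius_mm * mask$px_per_mm
  theta <- (180 - atan2(-dy, dx) * 180 / pi) %% 360
  if (window[2] >= 360 && window[1] > 0) {
    theta[theta == 0] <- 360
  }
  sel <- abs(r - r_target) <= annulus_halfwidth_px &
    theta >= window[1] & theta <= window[2]
  if (!any(sel)) abort("no vessel pixels.")
  mean(theta[sel])
}

#' Correlate vessel mean locations with RNFLT peak locations
#'
#' @param data A data frame with columns `vessel_angle_deg` and
#'   `peak_angle_deg` (one row per subject).
#' @return A one-row tibble from [pearson_r()].
#' @export
correlate_vessels_with_peaks <- function(data) {
  if (!all(c("vessel_angle_deg", "peak_angle_deg") %in% names(data))) {
    abort("`data` needs `vessel_angle_deg` and `peak_angle_deg` columns.")
  }
  pearson_r(data$vessel_angle_deg, data$peak_angle_deg)
}
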