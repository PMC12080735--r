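#' Plot a TSNIT profile
#'
#' @param profile A profile tibble, or a list of them (overlaid).
#' @param labels Optional character labels, one per profile.
#' @return A ggplot.
#' @export
plot_profile <- function(profile, labels = NULL) {
  if (is.data.frame(profile)) profile <- list(profile)
  labels <- labels %||% paste("profile", seq_along(profile))
  d <- purrr::map2_dfr(profile, labels, function(p, l) {
    dplyr::mutate(p, which = l)
  })
  ggplot2::ggplot(d, ggplot2::aes(.data$angle_deg, .data$thickness_um,
                                  colour = .data$which)) +
    ggplot2::geom_line() +
    tsnit_scale_x() +
    ggplot2::labs(x = "TSNIT angle (deg, 0 = CH9)",
                  y = "RNFLT (µm)", colour = NULL) +
    ggplot2::theme_minimal()
}

tsnit_scale_x <- function() {
  ggplot2::scale_x_continuous(
    breaks = seq(0, 360, 90),
    labels = c("T (0)", "S (90)", "N (180)", "I (270)", "T (360)")
  )
}

#' Plot a normative range with its categorization bands
#'
#' Per-angle mean with the normal (above the 95% lower limit), borderline
#' (between the 99% and 95% limits) and abnormal (below the 99% limit)
#' bands; optionally overlays an individual profile.
#'
#' @param object An `rnflt_normative`.
#' @param profile Optional profile tibble to overlay.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rnflt_normative <- function(object, profile = NULL, ...) {
  a <- object$angle
  top <- max(a$mean_um + 2 * a$sd_um)
  g <- ggplot2::ggplot(a, ggplot2::aes(.data$angle_deg)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower95_um, ymax = top),
                         fill = "darkgreen", alpha = 0.25) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower99_um,
                                      ymax = .data$lower95_um),
                         fill = "gold", alpha = 0.45) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = pmax(.data$lower99_um, 0) * 0,
                                      ymax = pmax(.data$lower99_um, 0)),
                         fill = "firebrick", alpha = 0.35) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean_um), linetype = 2) +
    tsnit_scale_x() +
    ggplot2::labs(x = "TSNIT angle (deg, 0 = CH9)", y = "RNFLT (µm)") +
    ggplot2::theme_minimal()
  if (!is.null(profile)) {
    g <- g + ggplot2::geom_line(
      data = profile,
      ggplot2::aes(.data$angle_deg, .data$thickness_um), colour = "blue"
    )
  }
  g
}

#' Plot per-clock-hour CoV before and after peak normalization
#'
#' @param object An `rnflt_pn_analysis`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rnflt_pn_analysis <- function(object, ...) {
  d <- tidyr::pivot_longer(
    object$cov_reduction,
    dplyr::starts_with("cov_"),
    names_to = "condition", values_to = "cov_pct",
    names_prefix = "cov_"
  )
  ggplot2::ggplot(d, ggplot2::aes(factor(.data$ch), .data$cov_pct,
                                  fill = .data$condition)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "Clock hour", y = "CoV (%)", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
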