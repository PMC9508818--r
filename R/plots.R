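# ggplot2 graphics: pseudorotation wheel and chi/delta covariance scatter.

#' Pseudorotation-wheel plot
#'
#' Polar plot of phase P (angle, 0 at the top, clockwise) against amplitude
#' nu_max (radius), one point per nucleotide, colored by chemistry.
#'
#' @param pucker Tibble from [sugar_pucker()] (or the `pucker` table of an
#'   `xna_report`).
#' @param label_points Label points with residue identifiers.
#' @return A ggplot object.
#' @export
plot_pucker_wheel <- function(pucker, label_points = TRUE) {
  df <- dplyr::filter(pucker, !.data$degenerate)
  df$id <- paste0(df$resid, df$resno)
  anchors <- tibble::tibble(
    P = c(18, 54, 90, 126, 162, 198, 234, 270, 306, 342),
    lab = c(
      "C3'-endo", "C4'-exo", "O4'-endo", "C1'-exo", "C2'-endo",
      "C3'-exo", "C4'-endo", "O4'-exo", "C1'-endo", "C2'-exo"
    )
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$P, y = .data$nu_max)) +
    ggplot2::geom_point(ggplot2::aes(color = .data$chemistry_id), size = 2.5) +
    ggplot2::geom_text(
      data = anchors, ggplot2::aes(x = .data$P, y = Inf, label = .data$lab),
      size = 2.8, vjust = 1, inherit.aes = FALSE
    ) +
    ggplot2::coord_polar(start = 0, direction = 1) +
    ggplot2::scale_x_continuous(
      limits = c(0, 360),
      breaks = seq(0, 342, by = 18), minor_breaks = NULL
    ) +
    ggplot2::labs(
      x = "pseudorotation phase P (deg)",
      y = expression(nu[max] ~ "(deg)"),
      color = "chemistry"
    ) +
    ggplot2::theme_minimal()
  if (label_points && nrow(df)) {
    p <- p + ggplot2::geom_text(
      ggplot2::aes(label = .data$id),
      size = 2.5, vjust = -1
    )
  }
  p
}

#' Chi/delta covariance scatter with A/B-form regions
#'
#' @param torsions Tibble from [backbone_torsions()] after [classify_form()]
#'   (or the `torsions` table of an `xna_report`).
#' @param regions Region boundaries (default [chi_delta_regions()]).
#' @return A ggplot object.
#' @export
plot_chi_delta <- function(torsions, regions = chi_delta_regions()) {
  df <- dplyr::filter(torsions, !is.na(.data$chi), !is.na(.data$delta_like))
  boxes <- tibble::tibble(
    form = c("A-form", "B-form"),
    xmin = c(regions$A$chi[1], regions$B$chi[1]),
    xmax = c(regions$A$chi[2], regions$B$chi[2]),
    ymin = c(regions$A$delta[1], regions$B$delta[1]),
    ymax = c(regions$A$delta[2], regions$B$delta[2])
  )
  ggplot2::ggplot(df, ggplot2::aes(x = wrap_angle(.data$chi), y = .data$delta_like)) +
    ggplot2::geom_rect(
      data = boxes,
      ggplot2::aes(
        xmin = .data$xmin, xmax = .data$xmax,
        ymin = .data$ymin, ymax = .data$ymax, fill = .data$form
      ),
      alpha = 0.15, inherit.aes = FALSE
    ) +
    ggplot2::geom_point(ggplot2::aes(color = .data$chemistry_id), size = 2.5) +
    ggplot2::labs(
      x = expression(chi ~ "(deg)"), y = expression(delta ~ "(deg)"),
      color = "chemistry", fill = "region"
    ) +
    ggplot2::theme_minimal()
}

#' Autoplot method for analysis reports
#'
#' @param object An `xna_report`.
#' @param which `"pucker"` (pseudorotation wheel) or `"chi_delta"`.
#' @param ... Passed to the underlying plot function.
#' @return A ggplot object.
#' @export
autoplot.xna_report <- function(object, which = c("pucker", "chi_delta"), ...) {
  which <- match.arg(which)
  if (which == "pucker") {
    plot_pucker_wheel(object$tables$pucker, ...)
  } else {
    plot_chi_delta(object$tables$torsions, ...)
  }
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
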