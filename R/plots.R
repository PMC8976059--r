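#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a 1D spectrum
#'
#' @param object An [nmr_spectrum()].
#' @param ... Unused.
#' @return A ggplot with the ppm axis reversed, NMR-style.
#' @export
autoplot.nmr_spectrum <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$ppm, y = .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "chemical shift (ppm)", y = "intensity (a.u.)") +
    ggplot2::theme_minimal()
}

#' Plot a phase trajectory
#'
#' Concentration, volume and mass of each phase against time, faceted by
#' quantity, with 95% ribbons when interval columns are present.
#'
#' @param object A `phase_trajectory`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.phase_trajectory <- function(object, ...) {
  long <- object |>
    dplyr::select("time_min", "phase", "C_mgml", "V_uL", "M_mg") |>
    tidyr::pivot_longer(c("C_mgml", "V_uL", "M_mg"),
                        names_to = "quantity", values_to = "value") |>
    dplyr::mutate(quantity = factor(
      .data$quantity, levels = c("C_mgml", "V_uL", "M_mg"),
      labels = c("concentration (mg/mL)", "volume (uL)", "mass (mg)")
    ))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_min, y = .data$value,
                                     colour = .data$phase)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "time (min)", y = NULL, colour = "phase") +
    ggplot2::theme_minimal()
}

#' Plot per-slice phase fractions over time
#'
#' @param object A `slice_profile`.
#' @param ... Unused.
#' @return A ggplot of dense percentage per slice against time.
#' @export
autoplot.slice_profile <- function(object, ...) {
  ggplot2::ggplot(
    object[object$usable, ],
    ggplot2::aes(x = .data$time_min, y = .data$dense_pct,
                 colour = factor(.data$center_mm))
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "time (min)", y = "dense phase (%)",
                  colour = "slice centre (mm)") +
    ggplot2::theme_minimal()
}

#' Plot a boundary settling fit
#'
#' @param object A `settling_fit`.
#' @param ... Unused.
#' @return A ggplot of boundary height against time with the fitted segments.
#' @export
autoplot.settling_fit <- function(object, ...) {
  d <- object$data
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$time_min, y = .data$boundary_mm)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "time (min)", y = "boundary height (mm)") +
    ggplot2::theme_minimal()
  if (!object$single_segment) {
    p <- p + ggplot2::geom_vline(xintercept = object$breakpoint_min,
                                 linetype = "dashed")
  }
  p
}
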