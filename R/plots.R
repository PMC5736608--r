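# ggplot2 autoplot methods for the result objects.

#' Plot a phase-power coupling profile
#'
#' Gamma power as a function of theta phase (two cycles shown, the field's
#' convention), with the mean direction marked.
#'
#' @param object A `pac_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pac_result
#' @export
autoplot.pac_result <- function(object, ...) {
  d <- object$bins
  d2 <- dplyr::bind_rows(
    dplyr::mutate(d, deg = .data$phase_center * 180 / pi),
    dplyr::mutate(d, deg = .data$phase_center * 180 / pi + 360)
  )
  ggplot2::ggplot(d2, ggplot2::aes(x = .data$deg, y = .data$mean_power)) +
    ggplot2::geom_col(width = 3.6, fill = "grey40") +
    ggplot2::geom_vline(
      xintercept = object$mean_direction * 180 / pi,
      linetype = "dashed", colour = "red"
    ) +
    ggplot2::labs(
      x = "theta phase (deg, 0 = peak)", y = "mean gamma power",
      title = sprintf(
        "%s theta → %s gamma, MRL = %.3f",
        object$phase_region, object$amp_region, object$mrl
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot a comodulogram
#'
#' Coupling strength (weighted MRL) as a heat map over phase frequency and
#' amplitude frequency.
#'
#' @param object A `comodulogram`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot comodulogram
#' @export
autoplot.comodulogram <- function(object, ...) {
  ggplot2::ggplot(
    tidy(object),
    ggplot2::aes(x = .data$phase_freq_hz, y = .data$amp_freq_hz, fill = .data$mrl)
  ) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(option = "inferno", name = "MRL") +
    ggplot2::labs(
      x = "phase frequency (Hz)", y = "amplitude frequency (Hz)",
      title = sprintf(
        "%s phase × %s power", object$phase_region, object$amp_region
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot an n:m phase-phase coupling matrix
#'
#' @param object A `phase_phase_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot phase_phase_result
#' @export
autoplot.phase_phase_result <- function(object, ...) {
  ggplot2::ggplot(
    tidy(object),
    ggplot2::aes(x = factor(.data$m), y = factor(.data$n), fill = .data$mrl)
  ) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "MRL", limits = c(0, 1)) +
    ggplot2::labs(x = "m (gamma multiplier)", y = "n (theta multiplier)") +
    ggplot2::theme_minimal()
}

#' Plot a spike cross-correlogram
#'
#' @param object A `ccg_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ccg_curve
#' @export
autoplot.ccg_curve <- function(object, ...) {
  ggplot2::ggplot(
    object$curve,
    ggplot2::aes(x = .data$lag_s * 1000, y = .data$value)
  ) +
    ggplot2::geom_col(width = 0.5, fill = "grey30") +
    ggplot2::labs(
      x = "lag (ms)", y = "normalized coincidences",
      title = sprintf("scalar CCG = %.3f", object$scalar_ccg)
    ) +
    ggplot2::theme_minimal()
}
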