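#' Plot a stimulus waveform
#'
#' @param object A waveform tibble (class `tact_waveform`).
#' @param ... Unused.
#' @return A ggplot object: displacement (um above the base indentation)
#'   against time.
#' @export
autoplot.tact_waveform <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time_s, .data$displacement_um)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(
      x = "time (s)", y = "displacement above base (µm)"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a psychometric fit
#'
#' Observed proportion of "change" responses per level (point size scaled by
#' trial count) with the fitted mixture curve, its asymptotes and the
#' corrected threshold (when valid).
#'
#' @param object A `psyfit` object.
#' @param n_grid Curve resolution.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.psyfit <- function(object, n_grid = 200, ...) {
  pts <- dplyr::mutate(object$data, phat = .data$k / .data$n)
  p <- ggplot2::ggplot(pts, ggplot2::aes(.data$level, .data$phat)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n), alpha = 0.7) +
    ggplot2::scale_size_area(max_size = 3, guide = "none") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed", colour = "grey50") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "stimulus level", y = "P(report change)") +
    ggplot2::theme_minimal()
  if (!is.null(object$params)) {
    grid <- tibble::tibble(
      level = seq(object$level_range[1], object$level_range[2],
                  length.out = n_grid)
    )
    grid$pred <- predict_psychometric(object$params, grid$level)
    p <- p + ggplot2::geom_line(
      data = grid, ggplot2::aes(.data$level, .data$pred), colour = "#2166ac"
    )
  }
  if (isTRUE(object$valid)) {
    p <- p + ggplot2::geom_vline(
      xintercept = object$threshold_corrected, colour = "grey30"
    )
  }
  p
}

#' Plot cohort thresholds by condition and gap
#'
#' @param records A threshold-record tibble from [fit_cohort()].
#' @return A ggplot object: valid percent-change thresholds per participant,
#'   split by condition, gap vs no-gap side by side.
#' @export
plot_thresholds <- function(records) {
  df <- records |>
    dplyr::filter(.data$valid) |>
    dplyr::mutate(gap = ifelse(.data$gap_ms > 0, "gap", "no gap"))
  ggplot2::ggplot(
    df,
    ggplot2::aes(.data$gap, .data$threshold_pct_change, group = .data$participant_id)
  ) +
    ggplot2::geom_line(alpha = 0.3) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::facet_wrap(~condition) +
    ggplot2::labs(x = NULL, y = "threshold (% change from reference)") +
    ggplot2::theme_minimal()
}
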