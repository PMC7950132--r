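# Uptake-plot rendering: deuterons incorporated versus time (minutes),
# mean +/- SEM per state, y-limit at the peptide's exchangeable-amide
# count.

#' Plot uptake curves
#'
#' One panel per peptide, deuterons versus time in minutes, points and
#' error bars (mean +/- SEM) coloured by state, with each panel's
#' y-axis running from 0 to the peptide's exchangeable-amide count.
#' Fitted exponentials, when supplied, are drawn as smooth lines.
#'
#' @param curves Output of [build_uptake_curves] (must carry
#'   `max_uptake`).
#' @param fits Optional output of [fit_uptake_curves].
#' @param peptides Optional character vector restricting which peptides
#'   are drawn.
#' @return A ggplot object.
#' @export
plot_uptake_curves <- function(curves, fits = NULL, peptides = NULL) {
  stopifnot("max_uptake" %in% names(curves))
  if (!is.null(peptides)) {
    curves <- dplyr::filter(curves, .data$peptide_id %in% peptides)
    if (!is.null(fits)) fits <- dplyr::filter(fits,
                                              .data$peptide_id %in% peptides)
  }
  curves <- dplyr::mutate(curves, time_min = .data$time_s / 60)
  limits <- curves |>
    dplyr::distinct(.data$peptide_id, .data$max_uptake) |>
    dplyr::mutate(time_min = 0)
  p <- ggplot2::ggplot(curves,
                       ggplot2::aes(x = .data$time_min, y = .data$mean_uptake,
                                    colour = .data$state)) +
    ggplot2::geom_point(size = 1.6) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_uptake - .data$sem,
                   ymax = .data$mean_uptake + .data$sem),
      width = 0.04, na.rm = TRUE) +
    ggplot2::geom_blank(data = limits, inherit.aes = FALSE,
                        mapping = ggplot2::aes(x = .data$time_min,
                                               y = .data$max_uptake)) +
    ggplot2::geom_blank(data = limits, inherit.aes = FALSE,
                        mapping = ggplot2::aes(x = .data$time_min, y = 0)) +
    ggplot2::facet_wrap(~peptide_id, scales = "free_y") +
    ggplot2::labs(x = "Time (min)", y = "Deuterons incorporated",
                  colour = "State") +
    ggplot2::theme_bw()
  if (!is.null(fits)) {
    fits_ok <- dplyr::filter(fits, .data$converged, !is.na(.data$k))
    if (nrow(fits_ok) > 0L) {
      grid <- fits_ok |>
        dplyr::group_by(.data$peptide_id, .data$state) |>
        dplyr::reframe(
          time_min = seq(0, max(curves$time_min), length.out = 60),
          mean_uptake = .data$A * (1 - exp(-.data$k * time_min * 60))
        )
      p <- p + ggplot2::geom_line(data = grid, linewidth = 0.4)
    }
  }
  p
}
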