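#' Plot fold geometry along a tension ramp
#'
#' One panel per normalised geometric readout as a function of the ramp
#' magnitude `|delta|` (the quasistatic analog of the time axis), with
#' mean and s.e.m. across replicates.
#'
#' @param object A `fold_ramp`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fold_ramp
#' @export
autoplot.fold_ramp <- function(object, ...) {
  gl <- glance(object)
  gl <- gl[gl$quantity %in% c("d_a_norm", "d_b_norm", "l_a_norm", "l_b_norm"), ]
  ggplot2::ggplot(gl, ggplot2::aes(x = abs(.data$delta), y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sem,
                                      ymax = .data$mean + .data$sem),
                         alpha = 0.25, fill = "steelblue") +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(
      x = expression("ramp magnitude " * abs(delta)),
      y = "value / h_tissue",
      title = paste("Quasistatic", object$protocol$mode, "ramp")) +
    ggplot2::theme_minimal()
}

#' Plot a tissue cross-section
#'
#' Apical and basal per-cell segments coloured by cell label; the fold
#' profile as seen in a section perpendicular to the fold.
#'
#' @param object A `cross_section`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cross_section
#' @export
autoplot.cross_section <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$y0, y = .data$z0,
                                   xend = .data$y1, yend = .data$z1,
                                   colour = .data$label,
                                   linetype = .data$layer)) +
    ggplot2::geom_segment(linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "section coordinate", y = "z (basal to apical)") +
    ggplot2::theme_minimal()
}

#' Plot a recoil track
#'
#' Separation of the two tracked vertices against time; the slope over the
#' first post-ablation frame is the recoil velocity `v0`.
#'
#' @param object A `recoil_track`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot recoil_track
#' @export
autoplot.recoil_track <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$separation)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::labs(x = "time after ablation", y = "vertex separation") +
    ggplot2::theme_minimal()
}

#' Plot a cross-correlation result
#'
#' Per-cell correlations as thin lines and the cell-averaged correlation in
#' bold, against the lag; a negative dip at positive lag means intensity
#' rises precede height drops.
#'
#' @param object An `xcorr_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot xcorr_result
#' @export
autoplot.xcorr_result <- function(object, ...) {
  long <- tidy(object) |>
    tidyr::pivot_longer(cols = dplyr::starts_with("cell_"),
                        names_to = "cell", values_to = "Ci")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$lag)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$Ci, group = .data$cell),
                       colour = "grey70", linewidth = 0.3, na.rm = TRUE) +
    ggplot2::geom_line(ggplot2::aes(y = .data$C), linewidth = 1, na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::labs(x = "time offset tau (s)",
                  y = "C(tau) = < g_a(t) g_h(t + tau) >") +
    ggplot2::theme_minimal()
}
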