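#' Plot an adsorbed spherocylinder configuration
#'
#' Draws the axis segment of every adsorbed particle; line width is
#' decorative, the hard-core diameter is not to scale.
#'
#' @param object An `rsa_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rsa_result <- function(object, ...) {
  p <- object$particles
  half <- p$L_nm / 2
  seg <- tibble::tibble(
    x = p$x_nm - half * cos(p$theta_rad),
    xend = p$x_nm + half * cos(p$theta_rad),
    y = p$y_nm - half * sin(p$theta_rad),
    yend = p$y_nm + half * sin(p$theta_rad))
  ggplot2::ggplot(seg, ggplot2::aes(x = .data$x, y = .data$y,
                                    xend = .data$xend,
                                    yend = .data$yend)) +
    ggplot2::geom_segment(linewidth = 0.4, alpha = 0.8) +
    ggplot2::coord_equal(xlim = c(0, object$box_side),
                         ylim = c(0, object$box_side)) +
    ggplot2::labs(x = "x [nm]", y = "y [nm]",
                  title = sprintf("coverage %.3f (jamming est. %.3f)",
                                  object$final_coverage,
                                  object$jamming_coverage)) +
    ggplot2::theme_minimal()
}

#' Plot a kinetic trace
#'
#' @param object A `kinetic_trace`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.kinetic_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s,
                                       y = .data$gamma_mg_m2,
                                       colour = .data$phase)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time [s]",
                  y = expression(Gamma ~ "[mg m"^-2 * "]")) +
    ggplot2::theme_minimal()
}

#' Plot a per-overtone QCM trace
#'
#' @param object A `qcm_trace`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.qcm_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s,
                                       y = .data$neg_dfreq_over_n_hz,
                                       colour = factor(.data$overtone))) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::labs(x = "time [s]", y = expression(-Delta * f / n[o] ~ "[Hz]"),
                  colour = "overtone") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
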