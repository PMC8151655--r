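# ggplot2 displays for the fitted-object classes

#' @describeIn fit_michaelis_menten substrate-velocity points with the
#'   fitted hyperbola.
#' @export
autoplot.mm_fit <- function(object, ...) {
  grid <- tibble(substrate_mM = seq(min(object$data$substrate_mM),
                                    max(object$data$substrate_mM),
                                    length.out = 200))
  grid$rate <- predict(object, grid$substrate_mM)
  ggplot2::ggplot(object$data,
                  ggplot2::aes(.data$substrate_mM, .data$rate)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::labs(x = "substrate (mM)", y = expression(v ~ (Delta * AU / min)),
                  title = sprintf("Km = %.3g mM, Vmax = %.3g",
                                  object$Km, object$Vmax)) +
    ggplot2::theme_minimal()
}

#' Lineweaver-Burk plot of a multi-dose kinetic series
#'
#' Double-reciprocal points with one OLS line per effector dose. Parallel
#' lines indicate uncompetitive inhibition; lines crossing on the y-axis
#' competitive; the control line lying above the others, activation.
#'
#' @param data tibble with `substrate_mM`, `dose_mM`, `rate`.
#' @return a ggplot.
#' @export
plot_lineweaver_burk <- function(data) {
  coords <- lineweaver_burk(data)
  lines <- attr(coords, "lines")
  ggplot2::ggplot(coords, ggplot2::aes(.data$inv_substrate, .data$inv_rate,
                                       colour = factor(.data$dose_mM))) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_abline(data = lines,
                         ggplot2::aes(slope = .data$slope,
                                      intercept = .data$intercept,
                                      colour = factor(.data$dose_mM))) +
    ggplot2::labs(x = "1 / [S] (1/mM)", y = "1 / v",
                  colour = "effector dose (mM)") +
    ggplot2::theme_minimal()
}

#' @describeIn classify_mechanism Lineweaver-Burk display of the classified
#'   series.
#' @export
autoplot.mechanism_fit <- function(object, ...) {
  plot_lineweaver_burk(object$data) +
    ggplot2::ggtitle(sprintf("mechanism: %s", object$label))
}

#' @describeIn fit_median_effect median-effect plot: logit effect versus
#'   log dose with the fitted line.
#' @export
autoplot.medfx_fit <- function(object, ...) {
  d <- mutate(object$data,
              log_dose = log10(.data$dose_mM),
              logit_fa = log10(.data$fa / (1 - .data$fa)))
  ggplot2::ggplot(d, ggplot2::aes(.data$log_dose, .data$logit_fa)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_abline(slope = object$m,
                         intercept = -object$m * log10(object$Dm),
                         colour = "steelblue") +
    ggplot2::labs(x = "log10 dose (mM)", y = "log10(fa / (1 - fa))",
                  title = sprintf("Dm = %.3g mM, m = %.3g (r = %.3f)",
                                  object$Dm, object$m, object$r)) +
    ggplot2::theme_minimal()
}

#' @describeIn combination_index dose-normalized isobologram; the dashed
#'   unit anti-diagonal is the Loewe-additivity line.
#' @export
autoplot.combo_result <- function(object, ...) {
  pts <- isobologram_points(object)
  ggplot2::ggplot(pts, ggplot2::aes(.data$d1_norm, .data$d2_norm,
                                    colour = .data$ratio,
                                    shape = factor(.data$x))) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_abline(slope = -1, intercept = 1, linetype = "dashed") +
    ggplot2::coord_equal(xlim = c(0, NA), ylim = c(0, NA)) +
    ggplot2::labs(x = expression(d[1] / D[x1]), y = expression(d[2] / D[x2]),
                  shape = "effect level x") +
    ggplot2::theme_minimal()
}
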