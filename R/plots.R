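#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a fitted standard curve over its data
#'
#' Data points with the fitted 4PL curve drawn over the predictor range.
#'
#' @param object An `fpl_fit`.
#' @param n_grid Number of grid points for the curve.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fpl_fit
#' @export
autoplot.fpl_fit <- function(object, n_grid = 200, ...) {
  rng <- range(object$data$predictor)
  grid <- tibble::tibble(predictor = seq(rng[1], rng[2], length.out = n_grid))
  grid$od <- eval_curve(object$params, object$model_form, grid$predictor)
  xlab <- if (object$model_form == "log") "ln(concentration, µg/L)" else "concentration (µg/L)"
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$predictor, y = .data$response)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$od), colour = "steelblue") +
    ggplot2::labs(x = xlab, y = "optical density",
                  title = sprintf("4PL standard curve (%s scale)", object$model_form)) +
    ggplot2::theme_minimal()
}

#' Plot concentration predictions with credible intervals
#'
#' One interval per predicted OD: the 95% interval as a thin bar, the 50%
#' interval as a thick bar, the median as a point. If `truth` is supplied the
#' true concentrations are overlaid as open diamonds.
#'
#' @param object A `conc_prediction` tibble.
#' @param truth Optional true concentrations, one per row.
#' @param log_scale Put the concentration axis on a log10 scale (default
#'   `TRUE`).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot conc_prediction
#' @export
autoplot.conc_prediction <- function(object, truth = NULL, log_scale = TRUE, ...) {
  d <- tidy(object)
  d$idx <- factor(seq_len(nrow(d)))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$idx)) +
    ggplot2::geom_linerange(ggplot2::aes(ymin = .data$ci95_lo, ymax = .data$ci95_hi),
                            linewidth = 0.4, colour = "grey50") +
    ggplot2::geom_linerange(ggplot2::aes(ymin = .data$ci50_lo, ymax = .data$ci50_hi),
                            linewidth = 1.4, colour = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(y = .data$median), size = 1.6) +
    ggplot2::labs(x = "well", y = "estimated concentration (µg/L)") +
    ggplot2::theme_minimal()
  if (!is.null(truth)) {
    d$truth <- truth
    p <- p + ggplot2::geom_point(data = d, ggplot2::aes(y = .data$truth),
                                 shape = 5, colour = "firebrick")
  }
  if (log_scale) p <- p + ggplot2::scale_y_log10()
  p
}

#' Plot per-well 95% interval widths for both model forms
#'
#' Interval width against true concentration for each form, the visual
#' counterpart of the width-ratio statistic.
#'
#' @param object A `model_comparison` with predictions available.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot model_comparison
#' @export
autoplot.model_comparison <- function(object, ...) {
  if (is.null(object$preds)) {
    stop_elisacal("comparison has no predictions to plot", "elisacal_invalid_config")
  }
  d <- purrr::imap_dfr(object$preds, function(p, fm) {
    tibble::tibble(form = fm, truth = object$test$effective_conc,
                   width = p$ci95_hi - p$ci95_lo)
  })
  ggplot2::ggplot(d, ggplot2::aes(x = .data$truth, y = .data$width,
                                  colour = .data$form)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "true concentration (µg/L)",
                  y = "95% interval width (µg/L)", colour = "curve form") +
    ggplot2::theme_minimal()
}
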