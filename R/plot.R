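#' Plot a dose-response curve
#'
#' Base-graphics plot of the estimated curve, with optional confidence
#' bounds and a rug of observed treatment values.
#'
#' @param x a `dose_response_curve`.
#' @param lower,upper optional CI bounds aligned with the grid.
#' @param rug optional vector of observed treatments for a rug plot.
#' @param ylab,xlab,main usual graphics labels.
#' @param ... passed to [plot()].
#' @export
plot.dose_response_curve <- function(x, lower = NULL, upper = NULL,
                                     rug = NULL,
                                     ylab = "expected outcome",
                                     xlab = "treatment level",
                                     main = sprintf("Dose-response (%s)",
                                                    x$method), ...) {
  ylim <- range(c(x$mu_hat, lower, upper), finite = TRUE)
  plot(x$grid, x$mu_hat, type = "n", ylim = ylim, xlab = xlab, ylab = ylab,
       main = main, ...)
  if (!is.null(lower) && !is.null(upper))
    graphics::polygon(c(x$grid, rev(x$grid)), c(lower, rev(upper)),
                      col = grDevices::adjustcolor("steelblue", 0.25),
                      border = NA)
  graphics::lines(x$grid, x$mu_hat, lwd = 2, col = "steelblue4")
  if (!is.null(rug)) graphics::rug(rug)
  invisible(x)
}

#' Plot bootstrap curves
#'
#' Two panels: the dose-response curve and the marginal-effect curve, each
#' with percentile confidence bands; a horizontal reference at zero on the
#' effect panel.
#'
#' @param x a `bootstrap_result`.
#' @param rug optional observed treatments.
#' @param ... passed through to the panel plots.
#' @export
plot.bootstrap_result <- function(x, rug = NULL, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  curve <- structure(list(grid = x$grid, mu_hat = x$point$mu,
                          method = x$method, n = NA_integer_),
                     class = "dose_response_curve")
  plot(curve, lower = x$ci_mu$lower, upper = x$ci_mu$upper, rug = rug, ...)
  ylim <- range(c(x$point$eff, x$ci_effect$lower, x$ci_effect$upper, 0),
                finite = TRUE)
  plot(x$effect_t, x$point$eff, type = "n", ylim = ylim,
       xlab = "treatment level", ylab = "marginal effect",
       main = "Marginal treatment effect")
  graphics::polygon(c(x$effect_t, rev(x$effect_t)),
                    c(x$ci_effect$lower, rev(x$ci_effect$upper)),
                    col = grDevices::adjustcolor("firebrick", 0.2),
                    border = NA)
  graphics::lines(x$effect_t, x$point$eff, lwd = 2, col = "firebrick4")
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}
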