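#' Plot a Patlak fit
#'
#' Patlak scatter (apparent volume of distribution against stretched
#' time) with the fitted line and the fitting interval shaded.
#'
#' @param object a [patlak_fit()].
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot patlak_fit
#' @export
autoplot.patlak_fit <- function(object, ...) {
  pts <- object$points |> dplyr::filter(.data$valid)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$t_stretch, y = .data$vd)) +
    ggplot2::annotate("rect", xmin = object$interval$lo,
                      xmax = object$interval$hi,
                      ymin = -Inf, ymax = Inf, alpha = 0.08, fill = "steelblue") +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::geom_abline(intercept = object$vp,
                         slope = object$ktrans / 60, colour = "firebrick") +
    ggplot2::labs(
      x = "stretched time (s)", y = expression(v[d] == C[t] / C[p]),
      title = sprintf("Patlak fit%s: Ktrans = %.4g /min, vp = %.4g",
                      if (object$fixed_vp) " (fixed vp)" else "",
                      object$ktrans, object$vp)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a hybrid fit
#'
#' Shows the Patlak scatter with both the Step-1 line and the final
#' (Step 2/3) line, making the effect of the leakage-corrected intercept
#' visible.
#'
#' @param object a [hybrid_fit()].
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot hybrid_fit
#' @export
autoplot.hybrid_fit <- function(object, ...) {
  pts <- object$points |> dplyr::filter(.data$valid)
  lines <- tibble(
    stage = c("step 1 (Patlak)", "final (hybrid)"),
    intercept = c(object$step1$vp, object$vp),
    slope = c(object$step1$ktrans, object$ktrans) / 60
  )
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$t_stretch, y = .data$vd)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::geom_abline(
      data = lines,
      ggplot2::aes(intercept = .data$intercept, slope = .data$slope,
                   colour = .data$stage)
    ) +
    ggplot2::labs(
      x = "stretched time (s)", y = expression(v[d] == C[t] / C[p]),
      colour = NULL,
      title = sprintf("Hybrid fit: Ktrans = %.4g /min, vp = %.4g",
                      object$ktrans, object$vp)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a concentration curve or signal series
#'
#' @param object a `conc_curve` or `dyn_series`.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot conc_curve
#' @export
autoplot.conc_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s, y = .data$conc_mM)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "concentration (mM)") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.conc_curve
#' @method autoplot dyn_series
#' @export
autoplot.dyn_series <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s, y = .data$si)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "signal intensity (a.u.)") +
    ggplot2::theme_minimal()
}

#' Plot Monte-Carlo percent-deviation summaries
#'
#' Mean (with +/- SD ribbon) of the percent deviation against noise
#' level, one panel per parameter, coloured by method.
#'
#' @param pd a tibble from [monte_carlo_pd()].
#' @return A ggplot.
#' @export
plot_pd_summary <- function(pd) {
  ggplot2::ggplot(
    pd,
    ggplot2::aes(x = 100 * .data$noise_level, y = 100 * .data$mean_pd,
                 colour = .data$method, fill = .data$method)
  ) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = 100 * (.data$mean_pd - .data$sd_pd),
                   ymax = 100 * (.data$mean_pd + .data$sd_pd)),
      alpha = 0.15, colour = NA
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~param, scales = "free_y") +
    ggplot2::labs(x = "noise level (%)", y = "percent deviation (%)",
                  colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}
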