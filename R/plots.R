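# ggplot2 diagnostics for the fitted-object classes.

.fit_curve <- function(x, n = 200) {
  pgrid <- seq(min(x$data$pressure_bar), max(x$data$pressure_bar),
               length.out = n)
  est <- coef(x)
  kern <- .pressure_kernel(pgrid, est[["dV"]], est[["dBeta"]],
                           x$temperature_K)
  tibble(pressure_bar = pgrid, y = est[[1]] * kern)
}

#' Plot a pressure fit
#'
#' Observed values with error bars against pressure, overlaid with the
#' fitted exponential-quadratic curve.
#'
#' @param object A `pressure_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pressure_fit <- function(object, ...) {
  ylab <- if (object$model == "kd") "Kd (uM)" else
    expression(k[obs] ~ (s^-1))
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$pressure_bar, y = .data$y)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$y - .data$y_err,
                   ymax = .data$y + .data$y_err),
      width = 0, na.rm = TRUE) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = .fit_curve(object), colour = "firebrick") +
    ggplot2::labs(x = "Pressure (bar)", y = ylab) +
    ggplot2::theme_bw()
}

#' Plot a KIE pressure profile
#'
#' KIE values with propagated error bars against pressure; when a
#' `kie_pressure_fit` is supplied its exponential-quadratic curve is
#' overlaid.
#'
#' @param profile Tibble from [compute_kie_profile()].
#' @param fit Optional `kie_pressure_fit`.
#' @return A ggplot object.
#' @export
plot_kie_profile <- function(profile, fit = NULL) {
  gg <- ggplot2::ggplot(profile,
                        ggplot2::aes(x = .data$pressure_bar, y = .data$kie)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$kie - .data$kie_err,
                   ymax = .data$kie + .data$kie_err), width = 0) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Pressure (bar)", y = "KIE") +
    ggplot2::theme_bw()
  if (!is.null(fit)) {
    est <- coef(fit)
    T <- fit$temperature_K %||% .default_T
    pgrid <- seq(min(profile$pressure_bar), max(profile$pressure_bar),
                 length.out = 200)
    curve <- tibble(
      pressure_bar = pgrid,
      kie = est[["kie0"]] * .pressure_kernel(pgrid, est[["ddV"]],
                                             est[["ddBeta"]], T))
    gg <- gg + ggplot2::geom_line(data = curve, colour = "firebrick")
  }
  gg
}

#' Plot a single-exponential transient fit
#'
#' @param object An `exp_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.exp_fit <- function(object, ...) {
  sign_a <- if (object$direction == "decay") 1 else -1
  d <- tibble(time_s = object$time,
              signal_au = object$signal,
              fitted = object$offset +
                sign_a * object$amplitude * exp(-object$k_obs * object$time))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_s)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$signal_au),
                        size = 0.6, alpha = 0.5) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "firebrick") +
    ggplot2::labs(x = "Time (s)", y = "Signal (AU)") +
    ggplot2::theme_bw()
}

#' Plot an error-weighted linear fit
#'
#' @param object A `wls_fit` (e.g. from [correlate_summary_table()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.wls_fit <- function(object, ...) {
  d <- object$data
  d$y_err <- 1 / sqrt(d$w)
  gg <- ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$y - .data$y_err,
                   ymax = .data$y + .data$y_err), width = 0) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "firebrick") +
    ggplot2::labs(
      x = object$x_param %||% "x", y = object$y_param %||% "y",
      subtitle = sprintf("adj. R^2 = %.2f", object$r2_adj)) +
    ggplot2::theme_bw()
  gg
}
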