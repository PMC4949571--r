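# Cross-system correlation of p-T KIE parameters by error-weighted linear
# regression with adjusted R-squared.

#' Error-weighted linear fit
#'
#' Weighted least-squares regression of `y` on `x` with weights
#' \eqn{1/\sigma_y^2}. The weighted coefficient of determination is
#' computed about the weighted mean,
#' \eqn{R^2_w = 1 - SS_{res,w}/SS_{tot,w}}, and adjusted as
#' \eqn{R^2_{adj} = 1 - (1 - R^2_w)(n-1)/(n-2)}. Parameter standard errors
#' are scaled by the reduced chi-squared (the `lm` convention). Errors in
#' `x` are ignored.
#'
#' @param x,y Numeric vectors (n ≥ 3).
#' @param y_err Positive standard errors of `y`; `NULL` for an ordinary
#'   (equal-weight) fit.
#' @return A `wls_fit` object with `slope`, `slope_err`, `intercept`,
#'   `intercept_err`, `r2_adj`, `r2`, `n`. Has [tidy()]/[glance()] methods.
#' @examples
#' weighted_linear_fit(1:5, 2 * (1:5) + 1, rep(0.1, 5))
#' @export
weighted_linear_fit <- function(x, y, y_err = NULL) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  if (!is.null(y_err)) ok <- ok & is.finite(y_err)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) abort("need at least 3 finite points",
                   class = "baroKIE_fit_failure")
  if (stats::var(x) == 0) abort("zero variance in x; slope undefined",
                                class = "baroKIE_fit_failure")
  if (is.null(y_err)) {
    w <- rep(1, n)
  } else {
    y_err <- y_err[ok]
    if (any(y_err < 0)) abort("y_err must be non-negative")
    w <- 1 / y_err^2
    # guard for exactly-known points (zero error, e.g. parameters fixed in
    # the source fits): cap their weight at the largest finite weight
    if (any(!is.finite(w))) {
      if (!any(is.finite(w))) w[] <- 1
      else w[!is.finite(w)] <- max(w[is.finite(w)])
    }
  }
  fit <- lm(y ~ x, weights = w)
  sm <- suppressWarnings(summary(fit))  # perfect fits are legitimate here
  ybar_w <- weighted.mean(y, w)
  ss_res <- sum(w * residuals(fit)^2)
  ss_tot <- sum(w * (y - ybar_w)^2)
  r2 <- 1 - ss_res / ss_tot
  r2_adj <- 1 - (1 - r2) * (n - 1) / (n - 2)
  structure(list(
    slope = coef(fit)[["x"]],
    slope_err = sm$coefficients["x", "Std. Error"],
    intercept = coef(fit)[["(Intercept)"]],
    intercept_err = sm$coefficients["(Intercept)", "Std. Error"],
    r2 = r2, r2_adj = r2_adj, n = n, fit = fit,
    data = tibble(x = x, y = y, w = w)
  ), class = "wls_fit")
}

#' @export
print.wls_fit <- function(x, ...) {
  cat(sprintf(
    "Error-weighted linear fit (n = %d): slope = %.4g +/- %.2g, intercept = %.4g +/- %.2g, adj. R^2 = %.3f\n",
    x$n, x$slope, x$slope_err, x$intercept, x$intercept_err, x$r2_adj))
  invisible(x)
}

#' Correlate two p-T KIE parameters across systems
#'
#' Error-weighted linear regression of one five-parameter KIE signature
#' column against another across a table of systems (one row per system,
#' as returned by [summarize_system()] or [kie_systems()]). Rows with
#' missing values in either variable are dropped and reported via the
#' `dropped` element. Only y-errors enter the weights; x-errors are
#' ignored. A parameter that was held fixed in the source fits (error 0,
#' e.g. a compressibility fixed to zero) enters with its weight capped at
#' the largest finite weight in the column rather than an infinite weight.
#'
#' @param tbl Summary table with columns `<param>` and `<param>_err` for
#'   each of `kie0`, `ddH`, `ddS`, `ddV`, `ddBeta`.
#' @param x_param,y_param Parameter names, each one of `"kie0"`, `"ddH"`,
#'   `"ddS"`, `"ddV"`, `"ddBeta"`.
#' @return A `wls_fit` object; the systems used are in `$data$system`,
#'   dropped systems in `$dropped`.
#' @examples
#' correlate_summary_table(kie_systems(), "ddH", "ddS")
#' @export
correlate_summary_table <- function(tbl, x_param, y_param) {
  pars <- c("kie0", "ddH", "ddS", "ddV", "ddBeta")
  if (!x_param %in% pars || !y_param %in% pars)
    abort(paste0("parameters must be one of: ", paste(pars, collapse = ", ")))
  x <- tbl[[x_param]]
  y <- tbl[[y_param]]
  y_err <- tbl[[paste0(y_param, "_err")]]
  ok <- is.finite(x) & is.finite(y) & !is.na(y_err)
  if (sum(ok) < 3)
    abort("fewer than 3 systems with finite values for this parameter pair",
          class = "baroKIE_fit_failure")
  out <- weighted_linear_fit(x[ok], y[ok], y_err[ok])
  out$x_param <- x_param
  out$y_param <- y_param
  if (!is.null(tbl$system)) {
    out$data$system <- tbl$system[ok]
    out$dropped <- tbl$system[!ok]
  }
  out
}
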