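# Fitting of rate (and Kd) series to the Eyring and exponential-quadratic
# pressure models, KIE profiles with error propagation, and assembly of the
# five-parameter p-T KIE signature of a system.

.validate_rate_series <- function(data, p, k, err, min_n = 4) {
  if (nrow(data) < min_n)
    abort(sprintf("need at least %d points for this fit (got %d)",
                  min_n, nrow(data)),
          class = "baroKIE_fit_failure")
  if (any(k <= 0)) abort("rate constants must be positive")
  if (!is.null(err) && any(err <= 0)) abort("errors must be positive")
  if (is.unsorted(p)) abort("axis must be sorted increasing")
  if (stats::var(p) == 0)
    abort("all axis values identical; fit is singular",
          class = "baroKIE_fit_failure")
  invisible(TRUE)
}

#' Fit the exponential-quadratic pressure model to a rate series
#'
#' Fits \eqn{k(p) = k_0\exp(-\Delta V^\ddagger p/RT)\exp(\Delta\beta^\ddagger
#' p^2/2RT)} to observed rate constants over a pressure grid by
#' Levenberg-Marquardt nonlinear least squares, yielding the zero-pressure
#' rate constant, activation volume and activation isothermal
#' compressibility of one isotope's reaction. By default the fit is
#' error-weighted (weights \eqn{1/\sigma^2}) and performed in direct
#' k-space; set `weighted = FALSE` for an unweighted fit or
#' `log_space = TRUE` to fit ln k (a weighted quadratic regression in p).
#' Parameter standard errors come from the covariance scaled by the reduced
#' chi-squared.
#'
#' @param data Data frame with pressure, rate and error columns.
#' @param p,k,err Column names (tidy-eval); defaults `pressure_bar`,
#'   `k_obs`, `k_err`.
#' @param T Temperature in kelvin (default 298.15).
#' @param weighted Use 1/err² weights (default `TRUE`).
#' @param log_space Fit ln k by weighted quadratic regression instead of
#'   direct nonlinear least squares (default `FALSE`).
#' @param model `"rate"` or `"kd"`; only affects parameter naming in the
#'   result (the functional form is identical).
#' @return A `pressure_fit` object: parameter tibble (`term`, `estimate`,
#'   `std.error`), 3×3 `covariance`, `chi2_red`, the data, and fit options.
#'   Use [tidy()], [glance()], [coef()], [autoplot()].
#' @examples
#' rates <- dplyr::filter(por_rates(), reaction == "hydride", isotope == "H")
#' fit_pressure_series(rates)
#' @export
fit_pressure_series <- function(data, p = pressure_bar, k = k_obs, err = k_err,
                                T = .default_T, weighted = TRUE,
                                log_space = FALSE,
                                model = c("rate", "kd")) {
  model <- arg_match(model)
  pp <- pull(data, {{ p }})
  kk <- pull(data, {{ k }})
  err_quo <- enquo(err)
  ee <- if (quo_is_null(err_quo)) NULL else pull(data, !!err_quo)
  ord <- order(pp)
  pp <- pp[ord]; kk <- kk[ord]; if (!is.null(ee)) ee <- ee[ord]
  .validate_rate_series(tibble(p = pp), pp, kk, ee, min_n = 4)
  if (weighted && is.null(ee))
    abort("weighted fit requested but no error column supplied")
  Rbar <- .const$R_bar
  n <- length(pp)

  if (log_space) {
    # ln k = ln k0 - dV p/RT + (dBeta/1000) p^2/(2RT): weighted quadratic LS
    y <- log(kk)
    w <- if (weighted) (kk / ee)^2 else rep(1, n)
    X <- cbind(lnk0 = 1, dV = -pp / (Rbar * T),
               dBeta = pp^2 / (2 * Rbar * T * 1000))
    wf <- lm.wfit(X, y, w)
    b <- wf$coefficients
    rss <- sum(w * wf$residuals^2)
    chi2_red <- rss / (n - 3)
    XtWX <- crossprod(X * sqrt(w))
    cov_log <- chol2inv(chol(XtWX)) * chi2_red
    # delta-method back to k0 scale for the first parameter
    est <- c(exp(b[["lnk0"]]), b[["dV"]], b[["dBeta"]])
    J <- diag(c(est[1], 1, 1))
    covm <- J %*% cov_log %*% t(J)
    se <- sqrt(diag(covm))
  } else {
    lnk <- log(kk)
    dV0 <- -coef(lm(lnk ~ pp))[[2]] * Rbar * T
    args <- list(
      kk ~ k0 * exp(-dV * pp / (Rbar * T)) *
        exp((dBeta / 1000) * pp^2 / (2 * Rbar * T)),
      start = list(k0 = kk[which.min(pp)], dV = dV0, dBeta = 0),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    )
    if (weighted) args$weights <- 1 / ee^2
    fit <- tryCatch(do.call(minpack.lm::nlsLM, args), error = function(e) {
      abort(paste0("pressure fit failed: ", conditionMessage(e)),
            class = "baroKIE_fit_failure")
    })
    est <- coef(fit)
    covm <- vcov(fit)  # already scaled by reduced chi-squared
    se <- sqrt(diag(covm))
    chi2_red <- summary(fit)$sigma^2
  }

  terms <- if (model == "kd") c("kd0", "dV", "dBeta") else c("k0", "dV", "dBeta")
  dimnames(covm) <- list(terms, terms)
  structure(list(
    params = tibble(term = terms, estimate = unname(est),
                    std.error = unname(se)),
    covariance = covm, chi2_red = chi2_red, n = n,
    temperature_K = T, weighted = weighted, log_space = log_space,
    model = model,
    data = tibble(pressure_bar = pp, y = kk,
                  y_err = if (is.null(ee)) NA_real_ else ee)
  ), class = "pressure_fit")
}

#' @export
coef.pressure_fit <- function(object, ...) {
  setNames(object$params$estimate, object$params$term)
}

#' @export
print.pressure_fit <- function(x, ...) {
  lab <- if (x$model == "kd") "Kd" else "rate"
  cat(sprintf("Exponential-quadratic pressure fit (%s, %s, T = %.2f K)\n",
              lab, if (x$weighted) "weighted" else "unweighted",
              x$temperature_K))
  print(x$params)
  cat(sprintf("reduced chi-squared: %.3g on %d points\n", x$chi2_red, x$n))
  invisible(x)
}

#' Fit the Eyring (or Arrhenius) equation to a temperature series
#'
#' Weighted linear regression of `ln(k/T)` on `1/T` (Eyring) or of `ln k` on
#' `1/T` (Arrhenius). The slope gives the activation enthalpy
#' \eqn{\Delta H^\ddagger = -R\cdot slope} (kJ·mol⁻¹) and the intercept the
#' activation entropy \eqn{\Delta S^\ddagger = R(intercept - \ln(k_B/h))}
#' (J·mol⁻¹·K⁻¹); in the Arrhenius variant the slope gives `Ea` and the
#' intercept `ln A`. Weights are \eqn{(k/\sigma)^2}, the inverse variances
#' of ln k.
#'
#' @param data Data frame with temperature, rate and (optional) error
#'   columns.
#' @param T,k,err Column names (tidy-eval); defaults `temperature_K`,
#'   `k_obs`, `k_err`.
#' @param parameterization `"eyring"` (default) or `"arrhenius"`.
#' @return An `eyring_fit` object with a parameter tibble (`dH`, `dS` in
#'   kJ·mol⁻¹ / J·mol⁻¹·K⁻¹, or `A`, `Ea`), plus `chi2_red` and `n`.
#' @examples
#' tser <- tibble::tibble(
#'   temperature_K = seq(278, 318, by = 5),
#'   k_obs = eyring_rate(eyring_params(40, -20), temperature_K),
#'   k_err = 0.03 * k_obs)
#' fit_eyring_series(tser)
#' @export
fit_eyring_series <- function(data, T = temperature_K, k = k_obs, err = k_err,
                              parameterization = c("eyring", "arrhenius")) {
  parameterization <- arg_match(parameterization)
  TT <- pull(data, {{ T }})
  kk <- pull(data, {{ k }})
  err_quo <- enquo(err)
  ee <- if (quo_is_null(err_quo)) NULL else pull(data, !!err_quo)
  if (length(unique(TT)) < 3)
    abort("need at least 3 distinct temperatures",
          class = "baroKIE_fit_failure")
  if (any(TT <= 0) || any(kk <= 0)) abort("T and k must be positive")
  w <- if (is.null(ee)) rep(1, length(kk)) else (kk / ee)^2
  x <- 1 / TT
  y <- if (parameterization == "eyring") log(kk / TT) else log(kk)
  fit <- lm(y ~ x, weights = w)
  sm <- summary(fit)
  b <- coef(fit); se <- sm$coefficients[, "Std. Error"]
  R <- .const$R_J
  if (parameterization == "eyring") {
    params <- tibble(
      term = c("dH", "dS"),
      estimate = c(-b[["x"]] * R / 1000,
                   (b[["(Intercept)"]] - log(.const$kB / .const$h)) * R),
      std.error = c(se[["x"]] * R / 1000, se[["(Intercept)"]] * R))
  } else {
    params <- tibble(
      term = c("A", "Ea"),
      estimate = c(exp(b[["(Intercept)"]]), -b[["x"]] * R / 1000),
      std.error = c(exp(b[["(Intercept)"]]) * se[["(Intercept)"]],
                    se[["x"]] * R / 1000))
  }
  structure(list(
    params = params, parameterization = parameterization,
    chi2_red = sm$sigma^2, n = length(kk), fit = fit,
    data = tibble(temperature_K = TT, k_obs = kk,
                  k_err = if (is.null(ee)) NA_real_ else ee)
  ), class = "eyring_fit")
}

#' @export
coef.eyring_fit <- function(object, ...) {
  setNames(object$params$estimate, object$params$term)
}

#' @export
print.eyring_fit <- function(x, ...) {
  cat(sprintf("%s fit (n = %d):\n",
              if (x$parameterization == "eyring") "Eyring" else "Arrhenius",
              x$n))
  print(x$params)
  invisible(x)
}

#' Build a KIE pressure profile from paired isotope rate series
#'
#' Forms the pointwise ratio KIE = k_H/k_D on a shared pressure grid with
#' first-order error propagation
#' \eqn{\sigma_{KIE} = KIE\sqrt{(\sigma_H/k_H)^2 + (\sigma_D/k_D)^2}}.
#' The two series must be measured on identical pressure grids at the same
#' temperature.
#'
#' @param h,d Data frames for the light and heavy isotope with columns
#'   `pressure_bar`, `k_obs`, `k_err`.
#' @param T Temperature (K) recorded on the profile (default 298.15).
#' @return A tibble with columns `pressure_bar`, `kie`, `kie_err` and a
#'   `temperature_K` attribute.
#' @examples
#' rates <- por_rates()
#' h <- dplyr::filter(rates, reaction == "hydride", isotope == "H")
#' d <- dplyr::filter(rates, reaction == "hydride", isotope == "D")
#' compute_kie_profile(h, d)
#' @export
compute_kie_profile <- function(h, d, T = .default_T) {
  h <- arrange(h, .data$pressure_bar)
  d <- arrange(d, .data$pressure_bar)
  if (nrow(h) != nrow(d) ||
      any(abs(h$pressure_bar - d$pressure_bar) > 1e-9))
    abort("H and D series must share an identical pressure grid",
          class = "baroKIE_fit_failure")
  kie <- h$k_obs / d$k_obs
  kie_err <- kie * sqrt((h$k_err / h$k_obs)^2 + (d$k_err / d$k_obs)^2)
  out <- tibble(pressure_bar = h$pressure_bar, kie = kie, kie_err = kie_err)
  attr(out, "temperature_K") <- T
  out
}

#' Fit the pressure dependence of a KIE profile
#'
#' Extracts the zero-pressure KIE (`kie0`), the isotopic activation-volume
#' difference \eqn{\Delta\Delta V^\ddagger = \Delta V^\ddagger_H - \Delta
#' V^\ddagger_D} (`ddV`) and the compressibility difference
#' \eqn{\Delta\Delta\beta^\ddagger} (`ddBeta`) by one of two routes:
#'
#' * `method = "difference"` (default): differences of two separate isotope
#'   pressure fits, with errors combined in quadrature —
#'   `kie0 = k0H/k0D`, `ddV = dV_H - dV_D`, `ddBeta = dBeta_H - dBeta_D`.
#'   Because the ratio of two exponential-quadratic pressure curves is
#'   itself such a curve, this is algebraically exact on noiseless data.
#' * `method = "direct"`: a weighted exponential-quadratic fit of the KIE
#'   profile itself (needs ≥ 4 points).
#'
#' @param profile A KIE profile from [compute_kie_profile()] (required for
#'   `"direct"`).
#' @param method `"difference"` or `"direct"`.
#' @param fit_h,fit_d `pressure_fit` objects of the individual isotopes
#'   (required for `"difference"`).
#' @param T Temperature (K) for the direct fit.
#' @return A `kie_pressure_fit` object with parameter tibble (`kie0`,
#'   `ddV`, `ddBeta`) and the method used.
#' @examples
#' rates <- por_rates()
#' h <- dplyr::filter(rates, reaction == "hydride", isotope == "H")
#' d <- dplyr::filter(rates, reaction == "hydride", isotope == "D")
#' fit_kie_pressure(fit_h = fit_pressure_series(h),
#'                  fit_d = fit_pressure_series(d))
#' @export
fit_kie_pressure <- function(profile = NULL,
                             method = c("difference", "direct"),
                             fit_h = NULL, fit_d = NULL, T = .default_T) {
  method <- arg_match(method)
  if (method == "difference") {
    if (is.null(fit_h) || is.null(fit_d))
      abort("method = \"difference\" needs both isotope pressure fits",
            class = "baroKIE_fit_failure")
    ph <- coef(fit_h); pd <- coef(fit_d)
    sh <- setNames(fit_h$params$std.error, fit_h$params$term)
    sd_ <- setNames(fit_d$params$std.error, fit_d$params$term)
    kie0 <- ph[["k0"]] / pd[["k0"]]
    kie0_err <- kie0 * sqrt((sh[["k0"]] / ph[["k0"]])^2 +
                            (sd_[["k0"]] / pd[["k0"]])^2)
    params <- tibble(
      term = c("kie0", "ddV", "ddBeta"),
      estimate = c(kie0, ph[["dV"]] - pd[["dV"]],
                   ph[["dBeta"]] - pd[["dBeta"]]),
      std.error = c(kie0_err,
                    sqrt(sh[["dV"]]^2 + sd_[["dV"]]^2),
                    sqrt(sh[["dBeta"]]^2 + sd_[["dBeta"]]^2)))
    out <- list(params = params, method = "difference",
                temperature_K = fit_h$temperature_K)
  } else {
    if (is.null(profile))
      abort("method = \"direct\" needs a KIE profile")
    T_use <- attr(profile, "temperature_K") %||% T
    f <- fit_pressure_series(profile, p = pressure_bar, k = kie,
                             err = kie_err, T = T_use)
    params <- f$params
    params$term <- c("kie0", "ddV", "ddBeta")
    out <- list(params = params, method = "direct", temperature_K = T_use,
                chi2_red = f$chi2_red, covariance = f$covariance)
  }
  structure(out, class = "kie_pressure_fit")
}

#' @export
coef.kie_pressure_fit <- function(object, ...) {
  setNames(object$params$estimate, object$params$term)
}

#' @export
print.kie_pressure_fit <- function(x, ...) {
  cat(sprintf("KIE pressure dependence (%s method):\n", x$method))
  print(x$params)
  invisible(x)
}

#' Assemble the five-parameter p-T KIE signature of a system
#'
#' Combines the Eyring and pressure fits of the two isotopes into the
#' standard five-parameter summary of a system's KIE pressure-temperature
#' dependence. Sign conventions follow the field's usage: thermal
#' differences are heavy-minus-light
#' (\eqn{\Delta\Delta H^\ddagger = \Delta H^\ddagger_D - \Delta
#' H^\ddagger_H}, likewise \eqn{\Delta\Delta S^\ddagger}), while pressure
#' differences are light-minus-heavy
#' (\eqn{\Delta\Delta V^\ddagger = \Delta V^\ddagger_H - \Delta
#' V^\ddagger_D}, likewise \eqn{\Delta\Delta\beta^\ddagger}). KIE0 is the
#' ratio of the zero-pressure rate constants. All errors combine in
#' quadrature. The thermal pair may be `NULL`, in which case the thermal
#' columns are `NA` (pressure-only studies).
#'
#' @param label System label for the summary row.
#' @param eyring_h,eyring_d `eyring_fit` objects (may be `NULL`).
#' @param pfit_h,pfit_d `pressure_fit` objects for each isotope.
#' @return A one-row tibble with columns `system`, `kie0`, `kie0_err`,
#'   `ddH`, `ddH_err`, `ddS`, `ddS_err`, `ddV`, `ddV_err`, `ddBeta`,
#'   `ddBeta_err`.
#' @examples
#' rates <- por_rates()
#' h <- dplyr::filter(rates, reaction == "hydride", isotope == "H")
#' d <- dplyr::filter(rates, reaction == "hydride", isotope == "D")
#' summarize_system("POR, hydride",
#'                  pfit_h = fit_pressure_series(h),
#'                  pfit_d = fit_pressure_series(d))
#' @export
summarize_system <- function(label, eyring_h = NULL, eyring_d = NULL,
                             pfit_h, pfit_d) {
  kp <- fit_kie_pressure(fit_h = pfit_h, fit_d = pfit_d,
                         method = "difference")
  est <- coef(kp)
  se <- setNames(kp$params$std.error, kp$params$term)
  if (!is.null(eyring_h) && !is.null(eyring_d)) {
    eh <- coef(eyring_h); ed <- coef(eyring_d)
    seh <- setNames(eyring_h$params$std.error, eyring_h$params$term)
    sed <- setNames(eyring_d$params$std.error, eyring_d$params$term)
    ddH <- ed[["dH"]] - eh[["dH"]]
    ddH_err <- sqrt(seh[["dH"]]^2 + sed[["dH"]]^2)
    ddS <- ed[["dS"]] - eh[["dS"]]
    ddS_err <- sqrt(seh[["dS"]]^2 + sed[["dS"]]^2)
  } else {
    ddH <- ddH_err <- ddS <- ddS_err <- NA_real_
  }
  tibble(system = label,
         kie0 = est[["kie0"]], kie0_err = se[["kie0"]],
         ddH = ddH, ddH_err = ddH_err, ddS = ddS, ddS_err = ddS_err,
         ddV = est[["ddV"]], ddV_err = se[["ddV"]],
         ddBeta = est[["ddBeta"]], ddBeta_err = se[["ddBeta"]])
}

#' Fit the pressure dependence of a dissociation constant
#'
#' Weighted nonlinear fit of \eqn{K_d(p) = K_{d,0}\exp(-\Delta V
#' p/RT)\exp(\Delta\beta p^2/2RT)} to a Kd-versus-pressure series — the
#' same engine as [fit_pressure_series()] applied to equilibrium constants
#' (parameters reported as `kd0`, `dV`, `dBeta`).
#'
#' @param data Data frame with pressure, Kd and error columns.
#' @param p,kd,err Column names (tidy-eval); defaults `pressure_bar`,
#'   `kd_uM`, `kd_err`.
#' @param T Temperature (K).
#' @param weighted Use 1/err² weights (default `TRUE`).
#' @return A `pressure_fit` object with `model = "kd"`.
#' @examples
#' truth <- kd_params(3.7, -15.9, 12.5)
#' kdtab <- tibble::tibble(
#'   pressure_bar = c(1, seq(250, 2000, 250)),
#'   kd_uM = kd_pressure(truth, pressure_bar),
#'   kd_err = 0.05 * kd_uM)
#' fit_kd_pressure(kdtab)
#' @export
fit_kd_pressure <- function(data, p = pressure_bar, kd = kd_uM, err = kd_err,
                            T = .default_T, weighted = TRUE) {
  fit_pressure_series(data, p = {{ p }}, k = {{ kd }}, err = {{ err }},
                      T = T, weighted = weighted, model = "kd")
}
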