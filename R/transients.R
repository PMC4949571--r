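# Extraction of observed rate constants from single-exponential kinetic
# transients and of apparent Kd values from hyperbolic binding titrations.

#' Fit a single-exponential transient
#'
#' Fits an absorbance transient to
#' `S(t) = offset + amplitude * exp(-k_obs * t)` (decay) or
#' `S(t) = offset - amplitude * exp(-k_obs * t)` (rise) by
#' Levenberg-Marquardt least squares, as used to extract observed rate
#' constants from laser-photolysis or stopped-flow traces. With
#' `direction = "auto"` the direction is chosen from the sign of the
#' end-minus-start signal change. The rate constant is seeded from a
#' log-linear regression of |S - S_inf| over the first decade of the decay,
#' so the fit needs no user-supplied starting values.
#'
#' If the fitted time window spans fewer than three half-lives of the
#' fitted rate, a `"short_window"` flag is recorded (and a warning issued):
#' the rate is then poorly constrained by the data.
#'
#' @param data A data frame with the time and signal columns (a transient).
#' @param time,signal Column names (tidy-eval) of the time (s) and signal
#'   (AU) variables. Defaults `time_s`, `signal_au`.
#' @param direction `"auto"` (default), `"decay"` or `"rise"`.
#' @return An object of class `exp_fit`: a list with `k_obs`, `k_err`,
#'   `amplitude`, `offset`, `direction`, `residual_rms`, `flags`, `n`, and
#'   the fitted model. [tidy()] returns the parameter table, [glance()] the
#'   fit summary.
#' @examples
#' tr <- simulate_transient(k_true = 100, window = 0.05, sigma = 0, seed = 1)
#' fit_single_exponential(tr)
#' @export
fit_single_exponential <- function(data, time = time_s, signal = signal_au,
                                   direction = c("auto", "decay", "rise")) {
  direction <- arg_match(direction)
  t <- pull(data, {{ time }})
  s <- pull(data, {{ signal }})
  if (length(t) < 10) abort("a transient needs at least 10 points")
  if (is.unsorted(t, strictly = TRUE) || t[1] < 0)
    abort("`time` must be strictly increasing and non-negative")

  # standardize the signal so the optimizer sees the same problem under any
  # affine rescaling of the data (k_obs is invariant by construction)
  s_loc <- mean(s); s_scale <- sd(s)
  if (s_scale == 0) abort("signal is constant; no kinetics to fit",
                          class = "baroKIE_fit_failure")
  s_raw <- s
  s <- (s - s_loc) / s_scale

  n_tail <- max(3L, ceiling(length(s) * 0.1))
  s_inf <- mean(tail(s, n_tail))
  a0 <- s[1] - s_inf
  if (direction == "auto") direction <- if (a0 >= 0) "decay" else "rise"

  # seed k from log-linear decay of |S - S_inf| over the first decade
  dev <- abs(s - s_inf)
  use <- which(dev > max(dev) / 10 & dev > 0)
  use <- use[seq_len(max(min(length(use), length(s)), 5L))]
  k0 <- tryCatch({
    sl <- coef(lm(log(dev[use]) ~ t[use]))[[2]]
    max(-sl, 1 / diff(range(t)))
  }, error = function(e) 1 / diff(range(t)))

  fit <- tryCatch(
    minpack.lm::nlsLM(
      s ~ off + a * exp(-k * t),
      start = list(off = s_inf, a = a0, k = k0),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                           ptol = 1e-15)
    ),
    error = function(e) {
      abort(paste0("single-exponential fit failed to converge: ",
                   conditionMessage(e)),
            class = "baroKIE_fit_failure")
    }
  )
  est <- coef(fit)
  if (est[["k"]] <= 0) {
    abort(sprintf("single-exponential fit gave non-positive rate (k = %.3g)",
                  est[["k"]]),
          class = "baroKIE_fit_failure")
  }
  se <- summary(fit)$coefficients[, "Std. Error"]
  flags <- character()
  span <- diff(range(t))
  if (span < 3 * log(2) / est[["k"]]) {
    flags <- c(flags, "short_window")
    warn("transient spans fewer than 3 half-lives of the fitted rate")
  }
  structure(list(
    k_obs = est[["k"]], k_err = se[["k"]],
    amplitude = abs(est[["a"]]) * s_scale,
    amplitude_err = se[["a"]] * s_scale,
    offset = est[["off"]] * s_scale + s_loc,
    offset_err = se[["off"]] * s_scale,
    direction = if (est[["a"]] >= 0) "decay" else "rise",
    residual_rms = sqrt(mean(residuals(fit)^2)) * s_scale,
    flags = flags, n = length(t), fit = fit,
    signal = s_raw, time = t
  ), class = "exp_fit")
}

#' Fit a hyperbolic binding titration
#'
#' Fits `response = base + amp * [E] / (Kd + [E])` to a titration of a
#' spectroscopic binding signal against enzyme (or ligand) concentration,
#' returning the apparent dissociation constant. The Kd is seeded at the
#' concentration of half-maximal response. If measurement errors are
#' supplied the fit is weighted by 1/err².
#'
#' A `"non_saturating"` flag (with warning) is recorded when the largest
#' concentration does not exceed the fitted Kd, and an `"unidentifiable"`
#' flag when the saturation amplitude is within two standard errors of
#' zero. A negative Kd at the optimum is an error.
#'
#' @param data Data frame holding the titration.
#' @param conc,response,err Column names (tidy-eval) for concentration
#'   (µM), response, and optional response errors. Defaults `enzyme_uM`,
#'   `response`, `NULL`.
#' @return Object of class `hyperbola_fit` with `kd`, `kd_err`, `amp`,
#'   `amp_err`, `base`, `base_err`, `flags`, `n`. Has [tidy()]/[glance()]
#'   methods.
#' @examples
#' tit <- tibble::tibble(enzyme_uM = c(2, 5, 10, 20, 50, 100, 200),
#'                       response = 0.2 + 0.8 * enzyme_uM / (3.7 + enzyme_uM))
#' fit_binding_hyperbola(tit)
#' @export
fit_binding_hyperbola <- function(data, conc = enzyme_uM, response = response,
                                  err = NULL) {
  x <- pull(data, {{ conc }})
  y <- pull(data, {{ response }})
  w <- NULL
  err_quo <- enquo(err)
  if (!quo_is_null(err_quo)) {
    e <- pull(data, !!err_quo)
    stopifnot(all(e > 0))
    w <- 1 / e^2
  }
  if (length(x) < 4) abort("a titration needs at least 4 concentration points")
  if (any(x < 0) || is.unsorted(x, strictly = TRUE))
    abort("concentrations must be non-negative and strictly increasing")
  if (diff(range(y)) == 0)
    abort("response is constant across concentrations; Kd is unidentifiable",
          class = "baroKIE_fit_failure")

  base0 <- y[1]
  amp0 <- y[length(y)] - y[1]
  half <- base0 + amp0 / 2
  kd0 <- tryCatch(stats::approx(y, x, xout = half, ties = "ordered")$y,
                  error = function(e) NA_real_)
  if (!is.finite(kd0) || kd0 <= 0) kd0 <- stats::median(x)

  args <- list(
    y ~ base + amp * x / (kd + x),
    start = list(base = base0, amp = amp0, kd = kd0),
    control = minpack.lm::nls.lm.control(maxiter = 500)
  )
  if (!is.null(w)) args$weights <- w
  fit <- tryCatch(do.call(minpack.lm::nlsLM, args), error = function(e) {
    abort(paste0("hyperbolic fit failed to converge: ", conditionMessage(e)),
          class = "baroKIE_fit_failure")
  })
  est <- coef(fit)
  if (est[["kd"]] < 0) {
    abort(sprintf("hyperbolic fit gave negative Kd (%.3g)", est[["kd"]]),
          class = "baroKIE_fit_failure")
  }
  se <- summary(fit)$coefficients[, "Std. Error"]
  flags <- character()
  if (max(x) < est[["kd"]]) {
    flags <- c(flags, "non_saturating")
    warn("titration does not reach the fitted Kd; Kd is an extrapolation")
  }
  if (abs(est[["amp"]]) < 2 * se[["amp"]]) {
    flags <- c(flags, "unidentifiable")
    warn("saturation amplitude is within 2 SE of zero; Kd poorly defined")
  }
  structure(list(
    kd = est[["kd"]], kd_err = se[["kd"]],
    amp = est[["amp"]], amp_err = se[["amp"]],
    base = est[["base"]], base_err = se[["base"]],
    flags = flags, n = length(x), fit = fit
  ), class = "hyperbola_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf(
    "Single-exponential %s fit: k_obs = %.4g +/- %.2g s^-1 (n = %d, rms = %.3g)\n",
    x$direction, x$k_obs, x$k_err, x$n, x$residual_rms))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.hyperbola_fit <- function(x, ...) {
  cat(sprintf("Hyperbolic binding fit: Kd = %.4g +/- %.2g uM (n = %d)\n",
              x$kd, x$kd_err, x$n))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}
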