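# broom-style tidy()/glance() methods for the fitted-object classes.

#' @export
tidy.pressure_fit <- function(x, ...) x$params

#' @export
glance.pressure_fit <- function(x, ...) {
  tibble(chi2_red = x$chi2_red, n = x$n, temperature_K = x$temperature_K,
         weighted = x$weighted, log_space = x$log_space, model = x$model)
}

#' @export
tidy.eyring_fit <- function(x, ...) x$params

#' @export
glance.eyring_fit <- function(x, ...) {
  tibble(chi2_red = x$chi2_red, n = x$n,
         parameterization = x$parameterization)
}

#' @export
tidy.kie_pressure_fit <- function(x, ...) x$params

#' @export
glance.kie_pressure_fit <- function(x, ...) {
  tibble(method = x$method, temperature_K = x$temperature_K)
}

#' @export
tidy.exp_fit <- function(x, ...) {
  tibble(term = c("k_obs", "amplitude", "offset"),
         estimate = c(x$k_obs, x$amplitude, x$offset),
         std.error = c(x$k_err, x$amplitude_err, x$offset_err))
}

#' @export
glance.exp_fit <- function(x, ...) {
  tibble(direction = x$direction, residual_rms = x$residual_rms, n = x$n,
         flags = paste(x$flags, collapse = ";"))
}

#' @export
tidy.hyperbola_fit <- function(x, ...) {
  tibble(term = c("kd", "amp", "base"),
         estimate = c(x$kd, x$amp, x$base),
         std.error = c(x$kd_err, x$amp_err, x$base_err))
}

#' @export
glance.hyperbola_fit <- function(x, ...) {
  tibble(n = x$n, flags = paste(x$flags, collapse = ";"))
}

#' @export
tidy.wls_fit <- function(x, ...) {
  tibble(term = c("intercept", "slope"),
         estimate = c(x$intercept, x$slope),
         std.error = c(x$intercept_err, x$slope_err))
}

#' @export
glance.wls_fit <- function(x, ...) {
  tibble(r2 = x$r2, r2_adj = x$r2_adj, n = x$n)
}
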