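# Independent brute-force oracles used to cross-check the nonlinear fit
# engines, plus small fixture builders. The oracles never call the fitting
# code they verify.

# grid-search oracle for the exponential-quadratic pressure model:
# minimizes the (weighted) SSR over a dense (k0, dV, dBeta) grid
grid_search_pressure <- function(p, k, w = rep(1, length(k)),
                                 T = 298.15,
                                 k0_range, dV_range, dBeta_range,
                                 n_grid = 41) {
  Rb <- physical_constants()$R_bar
  k0s <- seq(k0_range[1], k0_range[2], length.out = n_grid)
  dVs <- seq(dV_range[1], dV_range[2], length.out = n_grid)
  dBs <- seq(dBeta_range[1], dBeta_range[2], length.out = n_grid)
  best <- c(NA, NA, NA); best_ssr <- Inf
  for (dV in dVs) for (dB in dBs) {
    kern <- exp(-dV * p / (Rb * T)) * exp((dB / 1000) * p^2 / (2 * Rb * T))
    for (k0 in k0s) {
      ssr <- sum(w * (k - k0 * kern)^2)
      if (ssr < best_ssr) { best_ssr <- ssr; best <- c(k0, dV, dB) }
    }
  }
  setNames(best, c("k0", "dV", "dBeta"))
}

# grid-search oracle for the binding hyperbola: (kd, amp) grid with the
# baseline profiled out analytically (linear in base at fixed kd, amp)
grid_search_hyperbola <- function(conc, resp, kd_range, amp_range,
                                  n_grid = 201) {
  kds <- seq(kd_range[1], kd_range[2], length.out = n_grid)
  amps <- seq(amp_range[1], amp_range[2], length.out = n_grid)
  best <- c(NA, NA); best_ssr <- Inf
  for (kd in kds) {
    frac <- conc / (kd + conc)
    for (amp in amps) {
      base <- mean(resp - amp * frac)
      ssr <- sum((resp - base - amp * frac)^2)
      if (ssr < best_ssr) { best_ssr <- ssr; best <- c(kd, amp) }
    }
  }
  setNames(best, c("kd", "amp"))
}

# minimal pressure_fit stand-in built from known parameter values and SEs,
# for testing arithmetic that consumes fit objects
fake_pressure_fit <- function(k0, dV, dBeta, k0_se = 0, dV_se = 0,
                              dBeta_se = 0, T = 298.15) {
  structure(list(
    params = tibble::tibble(term = c("k0", "dV", "dBeta"),
                            estimate = c(k0, dV, dBeta),
                            std.error = c(k0_se, dV_se, dBeta_se)),
    covariance = diag(c(k0_se, dV_se, dBeta_se)^2),
    chi2_red = 1, n = 9, temperature_K = T, weighted = TRUE,
    log_space = FALSE, model = "rate",
    data = tibble::tibble(pressure_bar = numeric(), y = numeric(),
                          y_err = numeric())
  ), class = "pressure_fit")
}

por_series <- function(rx, iso) {
  dplyr::filter(por_rates(), reaction == rx, isotope == iso)
}
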