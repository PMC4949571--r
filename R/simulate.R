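# Seeded generators for every input the analysis pipeline consumes:
# isotope rate tables over a pressure grid, single-exponential transients,
# binding titrations and Kd(p) series, all produced from ground-truth
# forward-model parameters.
#
# A single user seed is expanded into independent per-stream child seeds so
# that adding a stream never shifts the random numbers of existing streams.

.child_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((abs(seed) * 48271 + h * 99991) %% 2147483647L)
}

# Table-1-style experimental pressure grid: 1 bar then 250-bar steps to 2 kbar
#' Default experimental pressure grid
#'
#' The 1 bar - 2 kbar grid in 250-bar increments used in the
#' high-pressure photolysis experiments (ambient pressure plus eight
#' elevated pressures).
#' @return Numeric vector of 9 pressures in bar.
#' @export
default_pressure_grid <- function() c(1, seq(250, 2000, by = 250))

#' Simulate an isotope pair of pressure-dependent rate tables
#'
#' Generates replicate observed rate constants
#' `k = pressure_rate(truth, p, T) * (1 + eps)` with i.i.d. Gaussian
#' relative noise `eps ~ N(0, sigma^2)` for each isotope on a shared
#' pressure grid, then reports the replicate mean and replicate SD — the
#' averaging convention of multi-shot photolysis experiments. Defaults
#' emulate the published POR design: the 9-point 1 bar-2 kbar grid, 298.15
#' K, 3 replicates and 8% relative noise (the printed rate errors are
#' roughly proportional at the 5-15% level).
#'
#' @param truth_h,truth_d [pressure_params()] ground truths per isotope.
#' @param pressures Pressure grid in bar.
#' @param T Temperature (K).
#' @param sigma Relative Gaussian noise SD (0 gives the noiseless model
#'   values with `k_err = sigma * k`).
#' @param replicates Replicates per pressure (≥ 1).
#' @param seed Integer seed; identical seeds give identical tables.
#' @param reaction Reaction label stored in the table.
#' @return A tibble in the standard rate-table schema: `pressure_bar`,
#'   `temperature_K`, `reaction`, `isotope`, `k_obs`, `k_err`.
#' @examples
#' simulate_rate_table(pressure_params(2.30e6, 6.6, 4.7),
#'                     pressure_params(1.03e6, 5.0, 9.5), seed = 1)
#' @export
simulate_rate_table <- function(truth_h, truth_d,
                                pressures = default_pressure_grid(),
                                T = .default_T, sigma = 0.08,
                                replicates = 3, seed = 1,
                                reaction = "simulated") {
  stopifnot(sigma >= 0, replicates >= 1, length(pressures) >= 1)
  truths <- list(H = truth_h, D = truth_d)
  purrr::map_dfr(c("H", "D"), function(iso) {
    k_true <- pressure_rate(truths[[iso]], pressures, T)
    set.seed(.child_seed(seed, paste0("rates_", iso)))
    if (sigma == 0) {
      k_obs <- k_true
      k_err <- sigma * k_true
    } else {
      draws <- matrix(
        k_true * (1 + rnorm(length(k_true) * replicates, sd = sigma)),
        nrow = length(k_true))
      k_obs <- rowMeans(draws)
      k_err <- if (replicates > 1) apply(draws, 1, sd) else sigma * k_obs
    }
    tibble(pressure_bar = pressures, temperature_K = T,
           reaction = reaction, isotope = iso,
           k_obs = k_obs, k_err = k_err)
  })
}

#' Simulate a single-exponential kinetic transient
#'
#' Generates an absorbance transient `S(t) = offset + a * exp(-k_true t)`
#' (signed `a`: positive for a decay, negative for a rise) with additive
#' Gaussian noise of standard deviation `sigma * |amplitude|`, emulating a
#' laser-photolysis trace. A window shorter than `3 / k_true` leaves the
#' plateau unobserved; such transients carry an `"under_sampled"`
#' attribute flag.
#'
#' @param k_true True rate constant (s⁻¹).
#' @param direction `"decay"` or `"rise"`.
#' @param window Observation window (s).
#' @param n_points Number of evenly spaced samples (default 500).
#' @param sigma Noise SD as a fraction of the amplitude.
#' @param seed Integer seed.
#' @param amplitude,offset Signal amplitude and baseline (AU).
#' @return Tibble with `time_s`, `signal_au`; attributes `k_true`,
#'   `direction` and `flags`.
#' @examples
#' simulate_transient(2.26e6, window = 5e-6, sigma = 0.05, seed = 7)
#' @export
simulate_transient <- function(k_true, direction = c("decay", "rise"),
                               window = 5 / k_true, n_points = 500,
                               sigma = 0.05, seed = 1,
                               amplitude = 0.05, offset = 0.1) {
  direction <- arg_match(direction)
  stopifnot(k_true > 0, window > 0, n_points >= 10, sigma >= 0)
  t <- seq(0, window, length.out = n_points)
  a <- if (direction == "decay") amplitude else -amplitude
  s <- offset + a * exp(-k_true * t)
  set.seed(.child_seed(seed, "transient"))
  if (sigma > 0) s <- s + rnorm(n_points, sd = sigma * amplitude)
  flags <- character()
  if (window < 3 / k_true) {
    flags <- "under_sampled"
    warn("transient window is shorter than 3/k_true; plateau unobserved")
  }
  out <- tibble(time_s = t, signal_au = s)
  attr(out, "k_true") <- k_true
  attr(out, "direction") <- direction
  attr(out, "flags") <- flags
  out
}

#' Simulate pressure-dependent binding titrations
#'
#' For each pressure, draws a hyperbolic titration
#' `response = base + amp * [E] / (Kd(p) + [E]) + noise` with `Kd(p)` from
#' the exponential-quadratic pressure model of the dissociation constant,
#' emulating ternary-complex formation monitored at increasing enzyme
#' concentrations under pressure. If the enzyme grid does not extend beyond
#' the largest Kd on the pressure grid, the affected titrations are
#' non-saturating and a warning is issued.
#'
#' @param truth A [kd_params()] ground truth.
#' @param pressures Pressure grid (bar).
#' @param enzyme_uM Enzyme concentration grid (µM), strictly increasing.
#' @param T Temperature (K).
#' @param sigma Additive noise SD as a fraction of `amp`.
#' @param seed Integer seed.
#' @param base,amp Baseline and saturation amplitude of the response.
#' @return A list with `titrations` (tibble: `pressure_bar`, `enzyme_uM`,
#'   `response`, `err`) and `kd_true` (tibble: `pressure_bar`, `kd_uM`).
#' @examples
#' sim <- simulate_kd_titrations(kd_params(3.7, -15.9, 12.5), seed = 3)
#' head(sim$titrations)
#' @export
simulate_kd_titrations <- function(truth,
                                   pressures = default_pressure_grid(),
                                   enzyme_uM = c(2, 5, 10, 20, 50, 100, 150, 200),
                                   T = .default_T, sigma = 0.03, seed = 1,
                                   base = 0.2, amp = 1.0) {
  stopifnot(inherits(truth, "kd_params"), sigma >= 0)
  if (is.unsorted(enzyme_uM, strictly = TRUE) || any(enzyme_uM < 0))
    abort("enzyme grid must be non-negative and strictly increasing")
  kd_true <- kd_pressure(truth, pressures, T)
  if (max(enzyme_uM) < max(kd_true))
    warn("enzyme grid does not span the largest Kd on the pressure grid; high-pressure titrations will be non-saturating")
  set.seed(.child_seed(seed, "titrations"))
  tit <- purrr::map_dfr(seq_along(pressures), function(i) {
    resp <- base + amp * enzyme_uM / (kd_true[i] + enzyme_uM)
    if (sigma > 0) resp <- resp + rnorm(length(enzyme_uM), sd = sigma * amp)
    tibble(pressure_bar = pressures[i], enzyme_uM = enzyme_uM,
           response = resp, err = max(sigma, 1e-12) * amp)
  })
  list(titrations = tit,
       kd_true = tibble(pressure_bar = pressures, kd_uM = kd_true))
}

#' Simulate a Kd-versus-pressure series
#'
#' Draws `kd = kd_pressure(truth, p, T) * (1 + eps)` with relative Gaussian
#' noise, the direct route to a Kd(p) table for pressure-model recovery
#' experiments (bypassing the per-pressure titration step).
#'
#' @inheritParams simulate_kd_titrations
#' @return Tibble with `pressure_bar`, `kd_uM`, `kd_err` (the known
#'   relative error `sigma * kd`).
#' @examples
#' simulate_kd_series(kd_params(3.7, -15.9, 12.5), sigma = 0.05, seed = 11)
#' @export
simulate_kd_series <- function(truth, pressures = default_pressure_grid(),
                               T = .default_T, sigma = 0.05, seed = 1) {
  stopifnot(inherits(truth, "kd_params"), sigma >= 0)
  kd_true <- kd_pressure(truth, pressures, T)
  set.seed(.child_seed(seed, "kd_series"))
  kd <- if (sigma > 0) kd_true * (1 + rnorm(length(kd_true), sd = sigma))
        else kd_true
  tibble(pressure_bar = pressures, kd_uM = kd,
         kd_err = pmax(sigma, 1e-12) * abs(kd))
}
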