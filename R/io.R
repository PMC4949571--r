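# Readers/writers for the standard CSV schemas and accessors for the
# packaged POR datasets.

.rate_cols <- c("pressure_bar", "temperature_K", "isotope", "k_obs", "k_err")

#' Read and write rate tables
#'
#' `read_rate_table()` reads a CSV of observed rate constants in the
#' standard schema (`pressure_bar`, `temperature_K`, `isotope`, `k_obs`,
#' `k_err`, optional `reaction`), validates it (required columns present,
#' numeric cells, no duplicate pressure within an isotope/reaction series)
#' and returns it sorted by reaction, isotope and pressure.
#' `write_rate_table()` writes the same schema with full double precision,
#' so a write/read round trip reproduces the values exactly.
#'
#' @param path File path.
#' @param x A rate table (tibble in the standard schema).
#' @return `read_rate_table()` returns a tibble; `write_rate_table()`
#'   returns `path` invisibly.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' write_rate_table(por_rates(), tf)
#' read_rate_table(tf)
#' @export
read_rate_table <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE,
                         progress = FALSE, col_types = readr::cols())
  missing_cols <- setdiff(.rate_cols, names(tbl))
  if (length(missing_cols))
    abort(paste0("rate table is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "baroKIE_parse_error")
  if (!"reaction" %in% names(tbl)) tbl$reaction <- "unspecified"
  for (cl in .rate_cols) {
    vals <- suppressWarnings(as.numeric(tbl[[cl]]))
    if (cl != "isotope" && any(is.na(vals))) {
      bad <- which(is.na(vals))[1]
      abort(sprintf("non-numeric value in column '%s' at data row %d",
                    cl, bad),
            class = "baroKIE_parse_error")
    }
  }
  dup <- tbl %>%
    dplyr::count(.data$reaction, .data$isotope, .data$pressure_bar) %>%
    filter(.data$n > 1)
  if (nrow(dup))
    abort(sprintf(
      "duplicate (pressure, isotope) entry: %s %s at %g bar",
      dup$reaction[1], dup$isotope[1], dup$pressure_bar[1]),
      class = "baroKIE_parse_error")
  tbl %>%
    mutate(across(all_of(setdiff(.rate_cols, "isotope")), as.numeric)) %>%
    arrange(.data$reaction, .data$isotope, .data$pressure_bar) %>%
    select(all_of(c("pressure_bar", "temperature_K", "reaction",
                    "isotope", "k_obs", "k_err")))
}

#' @rdname read_rate_table
#' @export
write_rate_table <- function(x, path) {
  stopifnot(all(.rate_cols %in% names(x)))
  readr::write_csv(x, path)
  invisible(path)
}

#' Packaged POR laser-photolysis datasets
#'
#' Accessors for the published protochlorophyllide oxidoreductase (POR)
#' high-pressure datasets shipped with the package:
#'
#' * `por_rates()`: observed rate constants (mean ± SD over replicate
#'   shots) for the sequential hydride and proton transfers, for both
#'   isotopes, at nine pressures from 1 bar to 2 kbar at 25 °C — four
#'   series of nine points in the standard rate-table schema.
#' * `por_pressure_params()`: the published exponential-quadratic
#'   pressure-fit parameters (`k0`, `dV`, `dBeta` with errors) for each of
#'   the four series.
#' * `kie_systems()`: the published five-parameter p-T KIE signatures
#'   (KIE0, ddH, ddS, ddV, ddBeta with errors) for eight H-transfer
#'   systems: MR, PETNR with NADPH and NADH, AADH, the two sequential POR
#'   transfers, and ascorbate/ferricyanide with and without TEA. For the
#'   two ascorbate rows the compressibility difference was fixed to zero
#'   in the source fits; their `ddBeta_err` is 0 to mark the fixed value.
#' * `pchlide_kd_params()`: the published pressure dependence of the
#'   Pchlide dissociation constant (`kd0` = 3.7 ± 0.4 µM, `dV` = −15.9 ±
#'   3.6 cm³·mol⁻¹, `dBeta` = 12.5 ± 2.5 cm³·mol⁻¹·kbar⁻¹ at 25 °C).
#'
#' @return Tibbles (`por_rates()`, `por_pressure_params()`,
#'   `kie_systems()`) or a list with a [kd_params()] `truth` and an `errs`
#'   vector (`pchlide_kd_params()`).
#' @examples
#' por_rates()
#' pchlide_kd_params()$truth
#' @export
por_rates <- function() {
  read_rate_table(system.file("extdata", "por_rate_constants.csv",
                              package = "baroKIE", mustWork = TRUE))
}

#' @rdname por_rates
#' @export
por_pressure_params <- function() {
  tibble(
    reaction = rep(c("hydride", "proton"), each = 2),
    isotope = rep(c("H", "D"), 2),
    k0 = c(2.30e6, 1.03e6, 2.35e4, 1.08e4),
    k0_err = c(0.09e6, 0.02e6, 0.04e4, 0.03e4),
    dV = c(6.6, 5.0, 1.7, 7.5),
    dV_err = c(2.2, 1.2, 1.0, 2.3),
    dBeta = c(4.7, 9.5, -4.7, 4.9),
    dBeta_err = c(2.0, 1.3, 1.1, 2.5))
}

#' @rdname por_rates
#' @export
kie_systems <- function() {
  readr::read_csv(system.file("extdata", "kie_system_summaries.csv",
                              package = "baroKIE", mustWork = TRUE),
                  show_col_types = FALSE, progress = FALSE)
}

#' @rdname por_rates
#' @export
pchlide_kd_params <- function() {
  list(truth = kd_params(kd0 = 3.7, dV = -15.9, dBeta = 12.5),
       errs = c(kd0 = 0.4, dV = 3.6, dBeta = 2.5))
}

#' Reproduce the POR pressure analysis from the packaged rate table
#'
#' Runs the full fixture pipeline: fits the exponential-quadratic pressure
#' model to each of the four packaged POR rate series, forms the
#' difference-method KIE signatures and the direct KIE-profile fits for
#' both transfers, and compares every parameter against its published
#' value. A parameter passes when |fitted − published| ≤ `tol` × combined
#' SE, where the combined SE adds the fit SE and the published SE in
#' quadrature.
#'
#' @param weighted Error-weight the pressure fits (default `TRUE`).
#' @param tol Tolerance in combined-SE units (default 1).
#' @return A `por_reproduction` object: list with `pressure` (per-series
#'   parameter comparison), `kie` (difference-method KIE signature
#'   comparison plus direct-fit KIE0), `fits`, and `n_pass`/`n_total`.
#' @examples
#' rep <- reproduce_por()
#' rep$pressure
#' @export
reproduce_por <- function(weighted = TRUE, tol = 1) {
  rates <- por_rates()
  printed <- por_pressure_params()
  combos <- dplyr::distinct(printed, .data$reaction, .data$isotope)
  fits <- purrr::pmap(combos, function(reaction, isotope) {
    ser <- filter(rates, .data$reaction == !!reaction,
                  .data$isotope == !!isotope)
    fit_pressure_series(ser, T = ser$temperature_K[1], weighted = weighted)
  })
  names(fits) <- paste(combos$reaction, combos$isotope, sep = "_")

  pressure_cmp <- purrr::map_dfr(seq_len(nrow(combos)), function(i) {
    f <- fits[[i]]
    pr <- printed[i, ]
    tibble(reaction = pr$reaction, isotope = pr$isotope,
           term = f$params$term,
           fitted = f$params$estimate, fitted_se = f$params$std.error,
           published = c(pr$k0, pr$dV, pr$dBeta),
           published_se = c(pr$k0_err, pr$dV_err, pr$dBeta_err))
  }) %>%
    mutate(combined_se = sqrt(.data$fitted_se^2 + .data$published_se^2),
           z = abs(.data$fitted - .data$published) / .data$combined_se,
           pass = .data$z <= tol)

  published_kie <- kie_systems() %>%
    filter(.data$system %in% c("POR, hydride", "POR, proton"))
  kie_cmp <- purrr::map_dfr(c("hydride", "proton"), function(rx) {
    s <- summarize_system(paste0("POR, ", rx),
                          pfit_h = fits[[paste0(rx, "_H")]],
                          pfit_d = fits[[paste0(rx, "_D")]])
    h <- filter(rates, .data$reaction == rx, .data$isotope == "H")
    d <- filter(rates, .data$reaction == rx, .data$isotope == "D")
    prof <- compute_kie_profile(h, d, T = h$temperature_K[1])
    direct <- fit_kie_pressure(prof, method = "direct")
    pub <- filter(published_kie, .data$system == paste0("POR, ", rx))
    tibble(system = s$system,
           term = c("kie0", "ddV", "ddBeta", "kie0_direct"),
           fitted = c(s$kie0, s$ddV, s$ddBeta, coef(direct)[["kie0"]]),
           fitted_se = c(s$kie0_err, s$ddV_err, s$ddBeta_err,
                         direct$params$std.error[1]),
           published = c(pub$kie0, pub$ddV, pub$ddBeta, pub$kie0),
           published_se = c(pub$kie0_err, pub$ddV_err, pub$ddBeta_err,
                            pub$kie0_err))
  }) %>%
    mutate(combined_se = sqrt(.data$fitted_se^2 + .data$published_se^2),
           z = abs(.data$fitted - .data$published) / .data$combined_se,
           pass = .data$z <= tol)

  structure(list(
    pressure = pressure_cmp, kie = kie_cmp, fits = fits,
    weighted = weighted, tol = tol,
    n_pass = sum(pressure_cmp$pass) + sum(kie_cmp$pass),
    n_total = nrow(pressure_cmp) + nrow(kie_cmp)
  ), class = "por_reproduction")
}

#' @export
print.por_reproduction <- function(x, ...) {
  cat(sprintf(
    "POR reproduction (%s fits, tolerance %.2g combined SE): %d/%d parameters pass\n",
    if (x$weighted) "weighted" else "unweighted", x$tol,
    x$n_pass, x$n_total))
  cat("\nPressure-fit parameters vs published:\n")
  print(x$pressure, n = Inf)
  cat("\nKIE signature vs published:\n")
  print(x$kie, n = Inf)
  invisible(x)
}
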