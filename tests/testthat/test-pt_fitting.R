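# Pressure and Eyring fits, KIE profiles, signature assembly.

test_that("noiseless pressure series are recovered exactly", {
  truth <- pressure_params(k0 = 5e5, dV = 4.2, dBeta = -3.1)
  tab <- simulate_rate_table(truth, truth, sigma = 0, seed = 1)
  h <- dplyr::filter(tab, isotope == "H")
  f <- fit_pressure_series(h, err = NULL, weighted = FALSE)
  expect_equal(unname(coef(f)), c(5e5, 4.2, -3.1), tolerance = 1e-8)
  # ln-space variant agrees on noiseless data
  f2 <- fit_pressure_series(h, err = NULL, weighted = FALSE,
                            log_space = TRUE)
  expect_equal(coef(f2), coef(f), tolerance = 1e-7)
})

test_that("the pressure-fit optimum matches a brute-force grid search", {
  p <- c(1, 500, 1000, 1500, 2000)
  set.seed(11)
  truth <- pressure_params(k0 = 1e4, dV = 6, dBeta = 3)
  k <- pressure_rate(truth, p) * (1 + rnorm(5, sd = 0.03))
  f <- fit_pressure_series(tibble::tibble(pressure_bar = p, k_obs = k),
                           err = NULL, weighted = FALSE)
  g <- grid_search_pressure(p, k, k0_range = c(0.9e4, 1.1e4),
                            dV_range = c(3, 9), dBeta_range = c(-2, 8),
                            n_grid = 61)
  expect_equal(coef(f)[["k0"]], g[["k0"]], tolerance = 0.02)
  expect_equal(coef(f)[["dV"]], g[["dV"]], tolerance = 0.2)
  expect_equal(coef(f)[["dBeta"]], g[["dBeta"]], tolerance = 0.3)
})

test_that("under-determined or singular pressure fits fail cleanly", {
  tab <- tibble::tibble(pressure_bar = c(1, 250, 500),
                        k_obs = c(1e4, 9e3, 8e3), k_err = rep(100, 3))
  expect_error(fit_pressure_series(tab), class = "baroKIE_fit_failure")
  same_p <- tibble::tibble(pressure_bar = rep(500, 5),
                           k_obs = runif(5, 900, 1100), k_err = rep(10, 5))
  expect_error(fit_pressure_series(same_p), class = "baroKIE_fit_failure")
})

test_that("noiseless Eyring series are recovered exactly", {
  truth <- eyring_params(dH = 40, dS = -20)
  tab <- tibble::tibble(temperature_K = seq(278, 318, by = 5),
                        k_obs = eyring_rate(truth, temperature_K),
                        k_err = 0.05 * k_obs)
  f <- fit_eyring_series(tab)
  expect_equal(coef(f)[["dH"]], 40, tolerance = 1e-8)
  expect_equal(coef(f)[["dS"]], -20, tolerance = 1e-8)
  expect_error(fit_eyring_series(tab[1, ]), class = "baroKIE_fit_failure")
})

test_that("Arrhenius and Eyring fits satisfy Ea = dH + R*Tbar", {
  truth <- eyring_params(dH = 40, dS = -20)
  tab <- tibble::tibble(temperature_K = seq(278, 318, by = 5),
                        k_obs = eyring_rate(truth, temperature_K),
                        k_err = 0.05 * k_obs)
  fa <- fit_eyring_series(tab, parameterization = "arrhenius")
  Tbar <- mean(tab$temperature_K)
  Ea_expect <- 40 + physical_constants()$R_J * Tbar / 1000
  expect_equal(coef(fa)[["Ea"]], Ea_expect, tolerance = 0.01)
})

test_that("KIE profiles apply the ratio and first-order error propagation", {
  h <- por_series("hydride", "H")
  d <- por_series("hydride", "D")
  prof <- compute_kie_profile(h, d)
  expect_equal(prof$kie[1], 2.2376237623762374, tolerance = 1e-12)
  expect_equal(prof$kie_err[1], 0.3375064769253524, tolerance = 1e-12)
  # identical series give KIE = 1 everywhere
  self <- compute_kie_profile(h, h)
  expect_equal(self$kie, rep(1, 9))
  # mismatched grids fail
  expect_error(compute_kie_profile(h, d[-1, ]),
               class = "baroKIE_fit_failure")
})

test_that("propagated KIE errors match Monte Carlo within 5%", {
  kH <- 2.26e6; sH <- 0.21e6; kD <- 1.01e6; sD <- 0.12e6
  prof <- compute_kie_profile(
    tibble::tibble(pressure_bar = 1, k_obs = kH, k_err = sH),
    tibble::tibble(pressure_bar = 1, k_obs = kD, k_err = sD))
  set.seed(99)
  draws <- (kH + rnorm(1e6, sd = sH)) / (kD + rnorm(1e6, sd = sD))
  expect_lt(abs(sd(draws) - prof$kie_err) / prof$kie_err, 0.05)
})

test_that("direct and difference KIE parameterizations agree on noiseless data", {
  th <- pressure_params(k0 = 2.3e6, dV = 6.6, dBeta = 4.7)
  td <- pressure_params(k0 = 1.03e6, dV = 5.0, dBeta = 9.5)
  tab <- simulate_rate_table(th, td, sigma = 0, seed = 1)
  h <- dplyr::filter(tab, isotope == "H")
  d <- dplyr::filter(tab, isotope == "D")
  fh <- fit_pressure_series(h, err = NULL, weighted = FALSE)
  fd <- fit_pressure_series(d, err = NULL, weighted = FALSE)
  diff_fit <- fit_kie_pressure(fit_h = fh, fit_d = fd)
  prof <- compute_kie_profile(
    dplyr::mutate(h, k_err = 1e-6 * k_obs),
    dplyr::mutate(d, k_err = 1e-6 * k_obs))
  direct_fit <- fit_kie_pressure(prof, method = "direct")
  expect_equal(coef(direct_fit), coef(diff_fit), tolerance = 1e-6)
  # the algebraic truth: ratio of the two curves is again the same form
  expect_equal(unname(coef(diff_fit)),
               c(2.3e6 / 1.03e6, 1.6, -4.8), tolerance = 1e-8)
})

test_that("difference method requires both isotope fits", {
  expect_error(fit_kie_pressure(fit_h = fake_pressure_fit(1e6, 5, 2)),
               class = "baroKIE_fit_failure")
})

test_that("system summaries apply the D-H / H-D sign conventions", {
  fh <- fake_pressure_fit(2.30e6, 6.6, 4.7)
  fd <- fake_pressure_fit(1.03e6, 5.0, 9.5)
  s <- summarize_system("POR, hydride", pfit_h = fh, pfit_d = fd)
  expect_equal(s$ddV, 1.6)
  expect_equal(s$ddBeta, -4.8)
  # proton pipeline identities from the published per-isotope parameters
  s2 <- summarize_system("POR, proton",
                         pfit_h = fake_pressure_fit(2.35e4, 1.7, -4.7),
                         pfit_d = fake_pressure_fit(1.08e4, 7.5, 4.9))
  expect_equal(s2$ddV, -5.8)
  expect_equal(s2$ddBeta, -9.6)
  # identical inputs: all differences zero, KIE0 = 1
  s3 <- summarize_system("self", pfit_h = fh, pfit_d = fh)
  expect_equal(s3$kie0, 1)
  expect_equal(s3$ddV, 0)
  expect_equal(s3$ddBeta, 0)
  # swapping H and D negates the pressure differences
  s4 <- summarize_system("swapped", pfit_h = fd, pfit_d = fh)
  expect_equal(s4$ddV, -s$ddV)
  expect_equal(s4$ddBeta, -s$ddBeta)
})

test_that("thermal differences are heavy-minus-light and antisymmetric", {
  tabH <- tibble::tibble(temperature_K = seq(278, 318, 5),
                         k_obs = eyring_rate(eyring_params(40, -20),
                                             temperature_K),
                         k_err = 0.05 * k_obs)
  tabD <- tibble::tibble(temperature_K = seq(278, 318, 5),
                         k_obs = eyring_rate(eyring_params(47, -5),
                                             temperature_K),
                         k_err = 0.05 * k_obs)
  eh <- fit_eyring_series(tabH); ed <- fit_eyring_series(tabD)
  fh <- fake_pressure_fit(1e6, 5, 2); fd <- fake_pressure_fit(5e5, 4, 1)
  s <- summarize_system("x", eh, ed, fh, fd)
  expect_equal(s$ddH, 7, tolerance = 1e-6)
  expect_equal(s$ddS, 15, tolerance = 1e-6)
  s_swap <- summarize_system("x", ed, eh, fh, fd)
  expect_equal(s_swap$ddH, -7, tolerance = 1e-6)
  expect_equal(s_swap$ddS, -15, tolerance = 1e-6)
})

test_that("refits of the packaged POR series reproduce the published hydride and proton-H parameters", {
  printed <- por_pressure_params()
  for (i in 1:3) {  # hydride H, hydride D, proton H
    pr <- printed[i, ]
    f <- fit_pressure_series(por_series(pr$reaction, pr$isotope))
    z <- abs(coef(f) - c(pr$k0, pr$dV, pr$dBeta)) /
      sqrt(tidy(f)$std.error^2 + c(pr$k0_err, pr$dV_err, pr$dBeta_err)^2)
    expect_true(all(z <= 1))
  }
})

test_that("parameter recovery is unbiased with near-nominal interval coverage", {
  truth <- pressure_params(k0 = 2.30e6, dV = 6.6, dBeta = 4.7)
  res <- purrr::map_dfr(1:200, function(i) {
    tab <- simulate_rate_table(truth, truth, sigma = 0.08, replicates = 3,
                               seed = 5000 + i)
    f <- fit_pressure_series(dplyr::filter(tab, isotope == "H"))
    tibble::tibble(dV = coef(f)[["dV"]],
                   dV_se = tidy(f)$std.error[2])
  })
  expect_lt(abs(median(res$dV) - 6.6), 0.5)
  coverage <- mean(abs(res$dV - 6.6) <= res$dV_se)
  expect_gte(coverage, 0.55)
  expect_lte(coverage, 0.80)
})

test_that("noiseless Kd series recover the published parameters exactly and 3 points fail", {
  truth <- pchlide_kd_params()$truth
  tab <- simulate_kd_series(truth, sigma = 0, seed = 1)
  f <- fit_kd_pressure(tab)
  expect_equal(unname(coef(f)), c(3.7, -15.9, 12.5), tolerance = 1e-6)
  expect_error(fit_kd_pressure(tab[1:3, ]), class = "baroKIE_fit_failure")
})
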