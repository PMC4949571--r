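# Closed-form forward models: frozen-value oracles, identities and
# qualitative behaviour.

test_that("Eyring rate reduces to kB*T/h with zero activation parameters", {
  k <- eyring_rate(eyring_params(dH = 0, dS = 0), T = 298.15)
  expect_equal(k, 6.212437991620116e12, tolerance = 1e-10)
})

test_that("raising the activation enthalpy by 5.7 kJ/mol divides the rate by ~10", {
  p1 <- eyring_params(dH = 40, dS = -20)
  p2 <- eyring_params(dH = 45.7, dS = -20)
  ratio <- eyring_rate(p2, 298) / eyring_rate(p1, 298)
  expect_equal(ratio, 0.10020750294100983, tolerance = 1e-10)
  expect_equal(ratio, 0.1, tolerance = 0.01)
})

test_that("zero-barrier Arrhenius rate equals the pre-exponential at any T", {
  ap <- eyring_params(A = 3.2e8, Ea = 0, parameterization = "arrhenius")
  expect_identical(eyring_rate(ap, c(250, 298.15, 400)), rep(3.2e8, 3))
})

test_that("Eyring and Arrhenius parameterizations are consistent at a reference T", {
  # A = (kB*T*e/h) exp(dS/R), Ea = dH + RT reproduce the same k(T)
  cn <- physical_constants()
  Tref <- 298.15
  ep <- eyring_params(dH = 35, dS = -12)
  A <- cn$kB * Tref * exp(1) / cn$h * exp(-12 / cn$R_J)
  Ea <- 35 + cn$R_J * Tref / 1000
  ap <- eyring_params(A = A, Ea = Ea, parameterization = "arrhenius")
  expect_equal(eyring_rate(ap, Tref), eyring_rate(ep, Tref),
               tolerance = 1e-10)
})

test_that("temperature domain errors are raised", {
  expect_error(eyring_rate(eyring_params(40, 0), T = -1),
               class = "baroKIE_domain_error")
  expect_error(pressure_rate(pressure_params(1, 1), p = 0, T = 0),
               class = "baroKIE_domain_error")
})

test_that("pressure model returns exactly k0 at zero pressure", {
  pp <- pressure_params(k0 = 2.30e6, dV = 6.6, dBeta = 4.7)
  expect_identical(pressure_rate(pp, p = 0), 2.30e6)
  kp <- kd_params(kd0 = 3.7, dV = -15.9, dBeta = 12.5)
  expect_identical(kd_pressure(kp, p = 0), 3.7)
})

test_that("pressure model matches hand evaluation of the published hydride-H fit", {
  pp <- pressure_params(k0 = 2.30e6, dV = 6.6, dBeta = 4.7)
  expect_equal(pressure_rate(pp, p = 2000, T = 298),
               1972973.1969685722, tolerance = 1e-12)
  # consistent with the printed 2 kbar observation 2.02 +/- 0.15e6
  expect_lt(abs(pressure_rate(pp, 2000, 298) - 2.02e6), 0.15e6)
})

test_that("with zero compressibility ln k is exactly linear in p", {
  pp <- pressure_params(k0 = 1e5, dV = 8, dBeta = 0)
  Rb <- physical_constants()$R_bar
  k <- pressure_rate(pp, c(0, 500, 1000, 2000), T = 298.15)
  expect_true(all(diff(k) < 0))  # dV > 0: strictly decreasing
  slopes <- diff(log(k)) / diff(c(0, 500, 1000, 2000))
  expect_equal(slopes, rep(-8 / (Rb * 298.15), 3), tolerance = 1e-12)
})

test_that("pressure kernel is invariant to coherent bar/kbar rescaling", {
  pp <- pressure_params(k0 = 2e6, dV = 6.6, dBeta = 4.7)
  p_bar <- c(1, 250, 1000, 2000)
  ref <- pressure_rate(pp, p_bar, T = 298.15)
  # same formula evaluated wholly in kbar units: R in cm^3 kbar mol^-1 K^-1
  Rk <- physical_constants()$R_bar / 1000
  p_kbar <- p_bar / 1000
  alt <- 2e6 * exp(-6.6 * p_kbar / (Rk * 298.15)) *
    exp(4.7 * p_kbar^2 / (2 * Rk * 298.15))
  expect_equal(ref, alt, tolerance = 1e-12)
})

test_that("Northrop model matches its closed-form values and limits", {
  np <- northrop_params(kie0 = 5, q_ratio = 1.4, dV_Q = 10)
  expect_equal(northrop_kie(np, p = 1000, T = 298),
               6.3358242894809855, tolerance = 1e-12)
  expect_equal(northrop_kie(np, p = 0), 5 * 1.4)
  # exponential limit: KIE -> kie0 as p -> infinity for dV_Q > 0
  expect_equal(northrop_kie(np, p = 1e9), 5, tolerance = 1e-8)
  # no tunnelling component: pressure-independent
  flat <- northrop_params(kie0 = 5, q_ratio = 1, dV_Q = 10)
  expect_identical(northrop_kie(flat, c(0, 500, 2000)), rep(5, 3))
})

test_that("vibronic model has the expected couplings and null behaviour", {
  base <- vibronic_params(kie0 = 1, E = 30, kappa0 = 3000, dKappa = 200,
                          r0 = 0.15, dR = 0.02)
  # no pressure coupling -> constant in p
  null <- vibronic_params(kie0 = 2, E = 30, kappa0 = 3000, dKappa = 0,
                          r0 = 0.15, dR = 0)
  v <- vibronic_kie(null, c(0, 1000, 2000))
  expect_equal(v, rep(v[1], 3))
  # increasing in kappa0 and r0, decreasing in T
  stiffer <- vibronic_params(1, E = 30, kappa0 = 3500, dKappa = 200,
                             r0 = 0.15, dR = 0.02)
  longer <- vibronic_params(1, E = 30, kappa0 = 3000, dKappa = 200,
                            r0 = 0.18, dR = 0.02)
  expect_gt(vibronic_kie(stiffer, 500), vibronic_kie(base, 500))
  expect_gt(vibronic_kie(longer, 500), vibronic_kie(base, 500))
  expect_gt(vibronic_kie(base, 500, T = 280), vibronic_kie(base, 500, T = 320))
  # domain error when the force constant turns non-positive on the grid
  soft <- vibronic_params(1, E = 30, kappa0 = 100, dKappa = -60,
                          r0 = 0.15, dR = 0.02)
  expect_error(vibronic_kie(soft, c(0, 2000)), class = "baroKIE_domain_error")
})

test_that("with fixed force constant the ln KIE curvature equals 2*E*dR^2", {
  vp <- vibronic_params(kie0 = 1.5, E = 30, kappa0 = 3000, dKappa = 0,
                        r0 = 0.2, dR = 0.02)
  lnk <- log(vibronic_kie(vp, p = c(0, 1000, 2000)))
  second_diff <- lnk[3] - 2 * lnk[2] + lnk[1]  # step = 1 kbar
  expect_equal(second_diff, 0.024, tolerance = 1e-12)
})

test_that("vibronic E can be derived from mode masses and frequencies", {
  # mu*omega difference of 2*hbar*1e20 m^-2-units gives E = 1 A^-2 exactly
  hbar <- physical_constants()$hbar
  vp <- vibronic_params(kie0 = 1, kappa0 = 3000, r0 = 0.2,
                        mu_h = 2 * hbar * 1e20, omega_h = 1,
                        mu_l = 0, omega_l = 1)
  expect_equal(vp$E, 1)
})

test_that("Kd pressure model reproduces the published Pchlide behaviour", {
  kp <- pchlide_kd_params()$truth
  expect_identical(kd_pressure(kp, p = 0), 3.7)
  expect_equal(kd_pressure(kp, p = 2000, T = 298.15),
               36.58431981005448, tolerance = 1e-12)
  # negative reaction volume: binding weakens monotonically with pressure
  mono <- kd_params(3.7, dV = -15.9, dBeta = 0)
  expect_true(all(diff(kd_pressure(mono, seq(0, 2000, 250))) > 0))
})
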