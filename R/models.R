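# Closed-form forward models for the pressure-temperature dependence of
# rate constants, dissociation constants and kinetic isotope effects.
#
# Unit contract (applies to every function in this file):
#   pressure p          bar (1 kbar = 1000 bar)
#   temperature T       K
#   rate constants      s^-1
#   activation volume   cm^3 mol^-1
#   compressibility     cm^3 mol^-1 kbar^-1 (converted internally to per-bar)
#   enthalpy            kJ mol^-1
#   entropy             J mol^-1 K^-1

.check_T <- function(T) {
  if (any(!is.finite(T)) || any(T <= 0)) {
    abort("temperature `T` must be finite and > 0 (kelvin)",
          class = "baroKIE_domain_error")
  }
}

#' Transition-state-theory parameter sets
#'
#' Constructors for the parameter objects consumed by the forward models.
#'
#' * `eyring_params()` holds the activation enthalpy \eqn{\Delta H^\ddagger}
#'   (kJ·mol⁻¹) and activation entropy \eqn{\Delta S^\ddagger}
#'   (J·mol⁻¹·K⁻¹) of the Eyring equation, or, with
#'   `parameterization = "arrhenius"`, the pre-exponential factor `A` (s⁻¹)
#'   and activation energy `Ea` (kJ·mol⁻¹).
#' * `pressure_params()` holds the zero-pressure rate constant `k0` (s⁻¹),
#'   activation volume `dV` (cm³·mol⁻¹) and activation isothermal
#'   compressibility `dBeta` (cm³·mol⁻¹·kbar⁻¹).
#' * `kd_params()` holds the analogous triple for an equilibrium
#'   dissociation constant: `kd0` (µM), reaction volume `dV` and
#'   compressibility `dBeta`.
#'
#' @param dH,dS Activation enthalpy (kJ·mol⁻¹) and entropy (J·mol⁻¹·K⁻¹).
#' @param A,Ea Arrhenius pre-exponential factor (s⁻¹) and activation energy
#'   (kJ·mol⁻¹); used when `parameterization = "arrhenius"`.
#' @param parameterization Either `"eyring"` (default) or `"arrhenius"`.
#' @param k0 Zero-pressure rate constant (s⁻¹), must be positive.
#' @param dV Activation (or reaction) volume (cm³·mol⁻¹).
#' @param dBeta Activation (or reaction) isothermal compressibility
#'   (cm³·mol⁻¹·kbar⁻¹).
#' @param kd0 Zero-pressure dissociation constant (µM), must be positive.
#' @return A classed list of parameters.
#' @seealso [eyring_rate()], [pressure_rate()], [kd_pressure()]
#' @examples
#' pressure_params(k0 = 2.30e6, dV = 6.6, dBeta = 4.7)
#' @export
eyring_params <- function(dH = NULL, dS = NULL, A = NULL, Ea = NULL,
                          parameterization = c("eyring", "arrhenius")) {
  parameterization <- arg_match(parameterization)
  if (parameterization == "eyring") {
    stopifnot(is.numeric(dH), is.numeric(dS), is.finite(dH), is.finite(dS))
    out <- list(dH = dH, dS = dS, parameterization = "eyring")
  } else {
    stopifnot(is.numeric(A), is.numeric(Ea), A > 0, is.finite(Ea))
    out <- list(A = A, Ea = Ea, parameterization = "arrhenius")
  }
  structure(out, class = "eyring_params")
}

#' @rdname eyring_params
#' @export
pressure_params <- function(k0, dV, dBeta = 0) {
  stopifnot(is.numeric(k0), k0 > 0, is.finite(dV), is.finite(dBeta))
  structure(list(k0 = k0, dV = dV, dBeta = dBeta), class = "pressure_params")
}

#' @rdname eyring_params
#' @export
kd_params <- function(kd0, dV, dBeta = 0) {
  stopifnot(is.numeric(kd0), kd0 > 0, is.finite(dV), is.finite(dBeta))
  structure(list(kd0 = kd0, dV = dV, dBeta = dBeta), class = "kd_params")
}

#' Tunnelling-model parameter sets
#'
#' * `northrop_params()` parameterizes the Northrop (Bell-correction based)
#'   model of a pressure-dependent KIE with a small tunnelling component:
#'   semiclassical `kie0`, tunnelling-component ratio `q_ratio` =
#'   \eqn{Q_H/Q_D}, and tunnelling activation volume `dV_Q` (cm³·mol⁻¹).
#' * `vibronic_params()` parameterizes the approximate vibronic
#'   (Marcus-like) model in which the transferred H tunnels between
#'   vibrational states and pressure modulates both the force constant of a
#'   promoting mode and the equilibrium donor-acceptor distance:
#'   pre-factor `kie0`; isotope mass-frequency term `E` (Å⁻²); zero-pressure
#'   force constant `kappa0` (kJ·mol⁻¹·Å⁻²) and its pressure coefficient
#'   `dKappa` (kJ·mol⁻¹·Å⁻²·kbar⁻¹); zero-pressure donor-acceptor distance
#'   `r0` (Å) and its compression coefficient `dR` (Å·kbar⁻¹).
#'
#' `E` may instead be derived from the reduced masses (kg) and angular
#' frequencies (rad·s⁻¹) of the heavy and light isotope modes as
#' \eqn{E = (\mu_h\omega_h - \mu_l\omega_l)/2\hbar}, converted to Å⁻².
#'
#' @param kie0 Dimensionless pre-factor / semiclassical KIE, positive.
#' @param q_ratio Tunnelling-component ratio \eqn{Q_H/Q_D}, positive.
#' @param dV_Q Tunnelling activation volume (cm³·mol⁻¹).
#' @param E Isotope mass-frequency term (Å⁻²).
#' @param kappa0,dKappa Promoting-mode force constant at zero pressure and
#'   its pressure coefficient.
#' @param r0,dR Equilibrium donor-acceptor distance at zero pressure (Å)
#'   and its compression per kbar (Å·kbar⁻¹).
#' @param mu_h,omega_h,mu_l,omega_l Optional reduced masses (kg) and angular
#'   frequencies (rad·s⁻¹) of the heavy/light isotope modes from which `E`
#'   is derived when `E` is not given directly.
#' @return A classed parameter list.
#' @seealso [northrop_kie()], [vibronic_kie()]
#' @examples
#' northrop_params(kie0 = 5, q_ratio = 1.4, dV_Q = 10)
#' @export
northrop_params <- function(kie0, q_ratio, dV_Q) {
  stopifnot(kie0 > 0, q_ratio > 0, is.finite(dV_Q))
  structure(list(kie0 = kie0, q_ratio = q_ratio, dV_Q = dV_Q),
            class = "northrop_params")
}

#' @rdname northrop_params
#' @export
vibronic_params <- function(kie0, E = NULL, kappa0, dKappa = 0, r0, dR = 0,
                            mu_h = NULL, omega_h = NULL,
                            mu_l = NULL, omega_l = NULL) {
  stopifnot(kie0 > 0, kappa0 > 0, r0 >= 0)
  if (is.null(E)) {
    if (is.null(mu_h) || is.null(omega_h) || is.null(mu_l) || is.null(omega_l))
      abort("supply either `E` or all of mu_h, omega_h, mu_l, omega_l")
    # (mu*omega) has units kg s^-1; /hbar gives m^-2; 1e-20 converts to A^-2
    E <- (mu_h * omega_h - mu_l * omega_l) / (2 * .const$hbar) * 1e-20
  }
  stopifnot(is.finite(E))
  structure(list(kie0 = kie0, E = E, kappa0 = kappa0, dKappa = dKappa,
                 r0 = r0, dR = dR),
            class = "vibronic_params")
}

#' Eyring / Arrhenius rate constant
#'
#' Evaluates the transition-state-theory rate constant
#' \deqn{k(T) = \frac{k_B T}{h}\exp(\Delta S^\ddagger/R)
#'   \exp(-\Delta H^\ddagger/RT)}
#' or, in the Arrhenius parameterization, \eqn{k(T) = A\exp(-E_a/RT)}.
#'
#' @param params An [eyring_params()] object.
#' @param T Temperature(s) in kelvin, all positive.
#' @return Rate constant(s) in s⁻¹, vectorized over `T`.
#' @examples
#' eyring_rate(eyring_params(dH = 40, dS = -20), T = 298.15)
#' @export
eyring_rate <- function(params, T = .default_T) {
  stopifnot(inherits(params, "eyring_params"))
  .check_T(T)
  if (params$parameterization == "arrhenius") {
    return(params$A * exp(-params$Ea * 1000 / (.const$R_J * T)))
  }
  .const$kB * T / .const$h *
    exp(params$dS / .const$R_J) *
    exp(-params$dH * 1000 / (.const$R_J * T))
}

# shared exponential-quadratic pressure kernel of the rate and Kd models:
# exp(-dV*p/RT) * exp(dBeta*p^2/2RT), p in bar, dBeta per kbar
.pressure_kernel <- function(p, dV, dBeta, T) {
  exp(-dV * p / (.const$R_bar * T)) *
    exp((dBeta / 1000) * p^2 / (2 * .const$R_bar * T))
}

#' Pressure dependence of a rate constant
#'
#' Evaluates
#' \deqn{k(p,T) = k_0 \exp(-\Delta V^\ddagger p/RT)
#'   \exp(\Delta\beta^\ddagger p^2/2RT)}
#' with `p` in bar, \eqn{\Delta V^\ddagger} in cm³·mol⁻¹,
#' \eqn{\Delta\beta^\ddagger} in cm³·mol⁻¹·kbar⁻¹ and
#' R = 83.1446 cm³·bar·mol⁻¹·K⁻¹, so at `p = 0` the function returns
#' exactly `k0`. A positive activation volume slows the reaction with
#' increasing pressure; the compressibility term curves ln k in p.
#'
#' @param params A [pressure_params()] object.
#' @param p Pressure(s) in bar (scalar or vector).
#' @param T Temperature(s) in kelvin.
#' @return Rate constant(s) in s⁻¹.
#' @examples
#' por <- pressure_params(k0 = 2.30e6, dV = 6.6, dBeta = 4.7)
#' pressure_rate(por, p = c(1, 1000, 2000))
#' @export
pressure_rate <- function(params, p, T = .default_T) {
  stopifnot(inherits(params, "pressure_params"))
  .check_T(T)
  params$k0 * .pressure_kernel(p, params$dV, params$dBeta, T)
}

#' Pressure dependence of a dissociation constant
#'
#' Evaluates \eqn{K_d(p) = K_{d,0}\exp(-\Delta V p/RT)\exp(\Delta\beta
#' p^2/2RT)} — the same exponential-quadratic form as [pressure_rate()]
#' applied to a binding equilibrium. A negative reaction volume makes
#' binding weaker (larger Kd) at higher pressure.
#'
#' @param params A [kd_params()] object.
#' @param p Pressure(s) in bar.
#' @param T Temperature(s) in kelvin.
#' @return Dissociation constant(s) in µM.
#' @examples
#' pchlide <- kd_params(kd0 = 3.7, dV = -15.9, dBeta = 12.5)
#' kd_pressure(pchlide, p = c(0, 1000, 2000))
#' @export
kd_pressure <- function(params, p, T = .default_T) {
  stopifnot(inherits(params, "kd_params"))
  .check_T(T)
  params$kd0 * .pressure_kernel(p, params$dV, params$dBeta, T)
}

#' Northrop model of a pressure-dependent KIE
#'
#' Evaluates the Bell-correction-based model for an observed KIE with a
#' small pressure-sensitive tunnelling component \eqn{Q}:
#' \deqn{KIE(p,T) = KIE_0 + KIE_0\,(Q_H/Q_D - 1)\exp(-\Delta V^Q p / RT).}
#' At `p = 0` this equals \eqn{KIE_0 \cdot Q_H/Q_D}; for a positive
#' tunnelling activation volume the observed KIE relaxes exponentially to
#' the semiclassical `kie0` as pressure increases.
#'
#' @param params A [northrop_params()] object.
#' @param p Pressure(s) in bar.
#' @param T Temperature(s) in kelvin.
#' @return Dimensionless KIE value(s).
#' @examples
#' northrop_kie(northrop_params(5, 1.4, 10), p = c(0, 1000))
#' @export
northrop_kie <- function(params, p, T = .default_T) {
  stopifnot(inherits(params, "northrop_params"))
  .check_T(T)
  params$kie0 +
    params$kie0 * (params$q_ratio - 1) *
      exp(-params$dV_Q * p / (.const$R_bar * T))
}

#' Approximate vibronic model of a pressure- and temperature-dependent KIE
#'
#' Evaluates the approximate vibronic (Marcus-like) expression
#' \deqn{KIE(p,T) \approx KIE_0
#'   \exp\!\left(\frac{-2 E\, k_B T}{\kappa_0 + \Delta\kappa\, p}\right)
#'   \exp\!\left(E\,(r_0 - \Delta r\, p)^2\right)}
#' in which pressure stiffens the promoting-mode force constant
#' (\eqn{\kappa_0 + \Delta\kappa p}) and compresses the equilibrium
#' donor-acceptor distance (\eqn{r_0 - \Delta r p}). `kB*T` enters per mole
#' (i.e. as RT in kJ·mol⁻¹) so that \eqn{k_B T/\kappa} has units Å² and both
#' exponents are dimensionless. With \eqn{\Delta\kappa = 0}, ln KIE is a
#' quadratic function of pressure, mirroring the exponential-quadratic
#' pressure dependence of observed rate constants.
#'
#' The typeset form of this expression is ambiguous about whether
#' \eqn{k_B T} multiplies or divides the force constant; the division form
#' implemented here is the only dimensionally consistent reading and gives
#' the expected signs (stiffening raises the KIE, heating lowers it). The
#' multiplication reading is not implemented.
#'
#' @param params A [vibronic_params()] object.
#' @param p Pressure(s) in bar. The force constant must remain positive over
#'   the whole requested grid, otherwise a domain error is raised.
#' @param T Temperature(s) in kelvin.
#' @return Dimensionless KIE value(s).
#' @examples
#' vp <- vibronic_params(kie0 = 1, E = 30, kappa0 = 3000, dKappa = 200,
#'                       r0 = 0.15, dR = 0.02)
#' vibronic_kie(vp, p = c(0, 1000, 2000))
#' @export
vibronic_kie <- function(params, p, T = .default_T) {
  stopifnot(inherits(params, "vibronic_params"))
  .check_T(T)
  p_kbar <- p / 1000
  kappa <- params$kappa0 + params$dKappa * p_kbar
  if (any(kappa <= 0)) {
    abort("force constant kappa0 + dKappa*p must stay positive over the pressure grid",
          class = "baroKIE_domain_error")
  }
  RT_kJ <- .const$R_J * T / 1000  # kB*T per mole, kJ mol^-1
  params$kie0 *
    exp(-2 * params$E * RT_kJ / kappa) *
    exp(params$E * (params$r0 - params$dR * p_kbar)^2)
}
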