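---
title: "Pressure-temperature analysis of kinetic isotope effects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pressure-temperature analysis of kinetic isotope effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(baroKIE)
library(dplyr)
```

## The scientific problem

Kinetic isotope effects (KIEs, e.g. $k_H/k_D$) and their temperature
dependence are the standard experimental probe of quantum-mechanical
hydrogen tunnelling in enzymes, and of the hypothesis that fast "promoting"
vibrations compress the hydrogen donor-acceptor distance and modulate the
tunnelling probability. Hydrostatic pressure offers a complementary
perturbation: semiclassical KIEs, set by zero-point-energy differences, are
nearly pressure-insensitive over the kbar range, so a pressure-dependent
KIE is often read as a tunnelling signature — though pressure-independent
KIEs occur in systems where tunnelling is independently established, so the
converse inference fails.

baroKIE implements the complete analysis chain for such
pressure-temperature (p-T) studies:

1. extraction of observed rate constants from single-exponential
   transients and of apparent $K_d$ values from hyperbolic binding
   titrations;
2. fitting of rate series to the Eyring equation (temperature axis) and to
   an exponential-quadratic pressure model (pressure axis);
3. construction of KIE pressure profiles with propagated errors and of the
   five-parameter p-T KIE signature of a system;
4. forward models for two tunnelling interpretations of a
   pressure-dependent KIE (Northrop/Bell and approximate vibronic);
5. error-weighted cross-system correlation of signature parameters;
6. seeded synthetic-data generators for every input, enabling end-to-end
   parameter-recovery experiments.

The package ships the published protochlorophyllide oxidoreductase (POR)
laser-photolysis dataset — observed hydride- and proton-transfer rate
constants for both isotopes at nine pressures (1 bar-2 kbar, 25 °C) — and
an eight-system summary table as fixtures, so the full published analysis
can be re-run with `reproduce_por()`.

## Models

**Eyring / Arrhenius (temperature axis).**
$k(T) = \frac{k_B T}{h} e^{\Delta S^\ddagger / R} e^{-\Delta H^\ddagger / RT}
      = A\,e^{-E_a/RT}.$
`fit_eyring_series()` performs a weighted linear regression of $\ln(k/T)$
on $1/T$ (weights $(k/\sigma)^2$, the inverse variances of $\ln k$). The
two parameterizations are linked by $A = (k_B T e/h)e^{\Delta S^\ddagger/R}$
and $E_a = \Delta H^\ddagger + RT$ at the reference temperature; the
Arrhenius variant is provided because much of the literature reports
$A$ and $E_a$.

**Exponential-quadratic pressure model (pressure axis).**
$k(p) = k_0\, e^{-\Delta V^\ddagger p / RT}\, e^{\Delta\beta^\ddagger p^2 / 2RT},$
where $\Delta V^\ddagger$ (cm³·mol⁻¹) is the apparent activation volume
(positive values: rates slow with pressure) and $\Delta\beta^\ddagger$
(cm³·mol⁻¹·kbar⁻¹) the activation isothermal compressibility, the
curvature of $\ln k$ in $p$. The same functional form describes the
pressure dependence of a dissociation constant
($K_d(p) = K_{d,0} e^{-\Delta V p/RT} e^{\Delta\beta p^2/2RT}$,
`fit_kd_pressure()`); for the POR-Pchlide complex, binding weakens with
pressure (negative $\Delta V$), so high-pressure experiments need
increasing enzyme concentrations to maintain a saturated ternary complex.

**The five-parameter KIE signature.** Substituting KIEs for rate constants
in the two equations above gives the descriptors $KIE_0$ (the KIE
extrapolated to zero pressure), $\Delta\Delta V^\ddagger$,
$\Delta\Delta\beta^\ddagger$ (pressure axis) and $\Delta\Delta H^\ddagger$,
$\Delta\Delta S^\ddagger$ (temperature axis). Sign conventions follow the
field's usage and differ between the axes: thermal differences are
heavy-minus-light ($\Delta\Delta H^\ddagger = \Delta H^{\ddagger D} -
\Delta H^{\ddagger H}$), pressure differences light-minus-heavy
($\Delta\Delta V^\ddagger = \Delta V^{\ddagger H} - \Delta V^{\ddagger D}$).
`summarize_system()` applies these conventions with errors in quadrature.

Because the ratio of two exponential-quadratic curves is itself such a
curve, the KIE pressure parameters can be obtained equivalently as
differences of the per-isotope fits (`method = "difference"`, the default
of `fit_kie_pressure()`) or by fitting the KIE profile directly
(`method = "direct"`). On noiseless data the two agree exactly; on real
data they differ slightly because the direct fit weights by the propagated
KIE errors. Both are provided since published analyses do not always state
which route was taken.

**Northrop (Bell-correction) model.**
$KIE(p) = KIE_0 + KIE_0\,(Q_H/Q_D - 1)\,e^{-\Delta V^Q p/RT}$
treats the observed KIE as a semiclassical part plus a small tunnelling
component $Q$ with its own activation volume; it is functionally close to
the exponential-quadratic form with zero compressibility, so $\Delta V^Q$
and $\Delta\Delta V^\ddagger$ are comparable. Note the typeset source
formula can be grouped either as implemented or as
$KIE_0[1 + (Q_H/Q_D - 1)e^{\cdot}]$ — the two are algebraically identical,
and at $p = 0$ the observable is $KIE_0\,Q_H/Q_D$, not $KIE_0$.

**Approximate vibronic model.**
$KIE(p,T) \approx KIE_0\,
 \exp\!\left(\frac{-2E\,k_BT}{\kappa_0 + \Delta\kappa\,p}\right)
 \exp\!\left(E\,(r_0 - \Delta r\,p)^2\right),
 \qquad E = \frac{\mu_h\omega_h - \mu_l\omega_l}{2\hbar},$
in which pressure stiffens a promoting-mode force constant $\kappa$ and
compresses the equilibrium donor-acceptor distance $r$. The typeset
rendering of this expression is ambiguous about whether $k_BT$ multiplies
or divides $(\kappa_0 + \Delta\kappa p)$; we adopt the division form
because it is the only dimensionally consistent reading ($k_BT/\kappa$ has
units Å² and $E$ units Å⁻², making both exponents dimensionless) and it
gives the physically expected signs — stiffening raises the KIE, heating
lowers it. The multiplication reading is documented here for completeness
but deliberately not implemented, to avoid silently mixing conventions.
With $\Delta\kappa = 0$ the model predicts $\ln KIE$ exactly quadratic in
$p$ with curvature $2E\,\Delta r^2$ per kbar² — a property the test suite
checks by finite differences. The full vibronic rate expression (Marcus
term, Franck-Condon integrals) is out of scope; only this approximate
closed form is provided.

## Units

Pressures are carried in bar, volumes in cm³·mol⁻¹, compressibilities in
cm³·mol⁻¹·kbar⁻¹ — the units in which such parameters are conventionally
tabulated — with $R = 83.1446$ cm³·bar·mol⁻¹·K⁻¹ in all pressure
exponents and $R = 8.31446$ J·mol⁻¹·K⁻¹ in thermal ones. The default
temperature is 298.15 K (25 °C). All forward models accept scalar or
vector pressure input.

## Fitting choices

* **Engine.** Nonlinear fits use Levenberg-Marquardt (minpack.lm) in
  direct $k$-space. An `log_space = TRUE` option fits $\ln k$ by weighted
  quadratic regression instead (with a delta-method back-transform of
  $k_0$); the two agree closely on well-behaved data and exactly on
  noiseless data. Direct $k$-space is the default because the measurement
  errors are reported on $k$, not $\ln k$.
* **Weighting.** Fits are error-weighted ($1/\sigma^2$) by default, with
  `weighted = FALSE` available. When the per-point errors are themselves
  noisy estimates — e.g. standard deviations of only 2-3 replicate shots —
  inverse-variance weighting can *inflate* the variance of the fitted
  parameters; the package's own recovery experiments (see the test suite)
  show exactly this on simulated 3-replicate tables, where unweighted fits
  recover the activation volume with dispersion matching the published
  standard errors while weighted fits are ~35% noisier. Both modes are
  therefore first-class.
* **Standard errors.** Parameter SEs come from the covariance scaled by
  the reduced $\chi^2$, the convention of the kinetics literature (it
  makes SEs independent of an overall misestimate of the measurement
  errors).
* **Initialization.** Deterministic, derivative-free starts: the pressure
  fit seeds $\Delta V^\ddagger$ from the log-linear slope of $\ln k$ vs
  $p$ and $\Delta\beta^\ddagger$ at 0; the exponential fit seeds $k$ from
  a log-linear regression of $|S - S_\infty|$; the hyperbola seeds $K_d$
  at the concentration of half-maximal response.
* **Error propagation.** KIE profiles use first-order propagation of the
  ratio. At the relative errors typical of these data
  ($\sigma/k \lesssim 0.12$) the first-order SE is within ~5% of the
  Monte-Carlo SD of the ratio; the discrepancy grows quadratically in
  $\sigma_D/k_D$, so profiles from very noisy heavy-isotope rates should
  be treated with care.
* **Degenerate inputs.** Under-determined series (< 4 points for 3
  parameters, < 3 distinct temperatures, zero axis variance) raise classed
  errors; non-saturating titrations, sub-3-half-life transients and
  amplitude-free titrations set warning flags rather than failing, since
  the fits remain formally defined.
* **Transient fitting.** The signal is standardized internally before
  optimization, making the fitted rate exactly invariant under affine
  rescaling of the data. A plain offset (no baseline-drift term) is
  assumed, matching the single-exponential convention of the source
  experiments. Replicate transients are fitted individually and combined
  as mean ± SD, not globally.
* **Binding fits.** The hyperbola is fitted without a ligand-depletion
  (tight-binding) correction, replicating the published convention even
  though the chromophore concentration is comparable to the $K_d$; the
  apparent $K_d$ values should be read accordingly.

## Error-weighted correlations

`correlate_summary_table()` regresses one signature parameter on another
across systems with weights $1/\sigma_y^2$, reporting the slope and the
adjusted weighted $R^2$ computed about the weighted mean,
$R^2_{adj} = 1 - (1 - R^2_w)(n-1)/(n-2)$. Two deliberate choices:
x-errors are ignored (no errors-in-variables treatment — the source
analyses say "error-weighted" without specifying one), so slopes are mildly
attenuated when x-errors are large; and parameters that were *fixed* in the
source fits (the ascorbate compressibility differences, fixed to 0) enter
with their weight capped at the largest finite weight in the column rather
than an infinite weight, keeping those rows from dominating the fit while
still using them. On the packaged eight-system table the entropy-enthalpy
difference correlation is strong and positive, the
$\Delta\Delta V^\ddagger$-$\Delta\Delta H^\ddagger$ slope negative, and the
compressibility difference uncorrelated — the published qualitative
picture:

```{r correlations}
tbl <- kie_systems()
for (y in c("ddS", "ddV", "ddBeta")) {
  f <- correlate_summary_table(tbl, "ddH", y)
  cat(sprintf("%-6s vs ddH: slope %6.2f +/- %.2f, adj R^2 %5.2f\n",
              y, f$slope, f$slope_err, f$r2_adj))
}
```

## The synthetic-data generators

The generators emulate the published POR experimental design: the 9-point
1 bar-2 kbar pressure grid in 250-bar steps, 25 °C, 3 replicates per
point, multiplicative Gaussian noise on rates (the printed errors are
roughly proportional to the rates, at the 5-15% level, so the default
relative noise is 8%), additive Gaussian noise on transients and
titrations, and reporting of replicate mean ± SD. A single user seed is
expanded into per-stream child seeds so that adding one more simulated
quantity never shifts the random numbers of existing streams, and every
generator is bit-reproducible under a fixed seed.

What the generators do *not* emulate: conformational heterogeneity
(pressure-shifted equilibria between reactive states, which can make the
KIE pressure dependence ill-defined under steady-state conditions),
baseline drift or correlated noise in transients, photophysics of the
excited chromophore, and any temperature dependence of the pressure
parameters. Passing recovery tests therefore demonstrate that the fitting
chain is unbiased and correctly calibrated *for data generated by the
models themselves* — they cannot certify the models against real data that
violate these assumptions.

## Problem sizes and numerical tolerances

The recovery experiments in the tests and the acceptance script use 200
seeded replicates per experiment (rate-table recovery, Kd(p) recovery,
titration recovery) and 10⁶ draws for Monte-Carlo checks of the error
propagation — sizes at which the Monte-Carlo error of the checked
statistic is well below the tolerances being asserted. Noiseless
round-trip recoveries are asserted at 10⁻⁶-10⁻⁸ relative; zero-pressure
identities are exact by construction (the $p = 0$ path multiplies by
exactly 1).

## Known limitations

* The pressure and temperature axes are fitted independently; no global
  p-T matrix fit is provided (the packaged dataset is single-temperature).
* The difference-method KIE signature inherits any bias of the individual
  isotope fits; the direct method inherits the first-order error
  propagation.
* Published parameter tables are printed to 2-3 significant figures;
  refitting from printed (rounded, replicate-averaged) data can land a
  published parameter slightly outside one combined standard error even
  when the analysis is faithful — the packaged reproduction reports one
  such case for the deuteron-transfer series, whose anomalous 2-kbar
  uptick dominates its curvature parameters.
* `weighted_linear_fit()` treats y-errors as exact; no errors-in-variables
  correction is applied anywhere.
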