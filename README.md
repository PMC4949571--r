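# baroKIE

Pressure-temperature analysis of kinetic isotope effects (KIEs) in enzyme
hydrogen-transfer reactions.

## What it does, and for whom

The temperature dependence of primary KIEs ($k_H/k_D$) is the standard
probe of quantum-mechanical H-tunnelling in enzymes; hydrostatic pressure
is a complementary perturbation, since semiclassical KIEs are nearly
insensitive to kbar-range pressure while tunnelling contributions need not
be. baroKIE is for experimentalists analysing such combined
pressure-temperature (p-T) datasets — stopped-flow or laser-photolysis
transients measured from 1 bar to ~2 kbar for two isotopes. It covers the
whole chain:

* **Transient analysis** — single-exponential fits of kinetic traces
  (`fit_single_exponential()`) and hyperbolic binding titrations
  (`fit_binding_hyperbola()`).
* **Pressure and temperature fits** — the exponential-quadratic pressure
  model
  $k(p) = k_0\,e^{-\Delta V^\ddagger p/RT}\,e^{\Delta\beta^\ddagger p^2/2RT}$
  (`fit_pressure_series()`, also for $K_d(p)$ via `fit_kd_pressure()`)
  and the Eyring/Arrhenius equation (`fit_eyring_series()`).
* **KIE signatures** — KIE pressure profiles with propagated errors
  (`compute_kie_profile()`) and the five-parameter p-T signature
  ($KIE_0$, $\Delta\Delta H^\ddagger$, $\Delta\Delta S^\ddagger$,
  $\Delta\Delta V^\ddagger$, $\Delta\Delta\beta^\ddagger$) via
  `fit_kie_pressure()` and `summarize_system()`.
* **Tunnelling forward models** — the Northrop/Bell form
  (`northrop_kie()`) and an approximate vibronic model with
  pressure-dependent promoting-mode stiffness and donor-acceptor distance
  (`vibronic_kie()`).
* **Cross-system correlation** — error-weighted linear fits with adjusted
  R² (`weighted_linear_fit()`, `correlate_summary_table()`).
* **Synthetic data** — seeded generators for rate tables, transients,
  titrations and $K_d(p)$ series (`simulate_*()`), for parameter-recovery
  experiments.

The published protochlorophyllide oxidoreductase (POR) high-pressure
photolysis dataset (four 9-point rate series: hydride/proton transfer ×
H/D, 1 bar-2 kbar at 25 °C) and an eight-system KIE-signature table ship
as fixtures (`por_rates()`, `por_pressure_params()`, `kie_systems()`,
`pchlide_kd_params()`); `reproduce_por()` re-runs the published analysis
end to end and reports parameter-by-parameter agreement.

All user-facing functions take a data frame first and return tibbles or
tidy-able fit objects (`tidy()`, `glance()`, `autoplot()`), so analyses
chain with the pipe.

## Worked example

Fit the pressure dependence of the POR hydride transfer and assemble its
KIE signature:

```r
library(baroKIE)
library(dplyr)

rates <- por_rates()
h <- filter(rates, reaction == "hydride", isotope == "H")
d <- filter(rates, reaction == "hydride", isotope == "D")

fit_h <- fit_pressure_series(h)
fit_h
#> Exponential-quadratic pressure fit (rate, weighted, T = 298.15 K)
#> # A tibble: 3 × 3
#>   term    estimate std.error
#>   <chr>      <dbl>     <dbl>
#> 1 k0    2298519.    92122.
#> 2 dV          6.56      2.18
#> 3 dBeta       4.63      2.03
#> reduced chi-squared: 0.314 on 9 points

summarize_system("POR, hydride", pfit_h = fit_h,
                 pfit_d = fit_pressure_series(d)) |>
  select(system, kie0, kie0_err, ddV, ddV_err, ddBeta, ddBeta_err)
#>         system kie0 kie0_err ddV ddV_err ddBeta ddBeta_err
#> 1 POR, hydride 2.22   0.0992 1.4    2.43  -5.11       2.33
```

Reading the numbers: the zero-pressure hydride-transfer rate is
2.30 × 10⁶ s⁻¹ with a small positive activation volume
(ΔV‡ = 6.6 ± 2.2 cm³·mol⁻¹ — the rate decreases mildly with pressure) and
positive activation compressibility (ln k curves upward in p). The
zero-pressure KIE is ≈ 2.2 and both isotope-difference pressure
parameters are small — the KIE decreases with pressure mainly through the
compressibility difference. All three agree with the published values for
this system within one combined standard error.

Cross-system correlation of the signature parameters:

```r
correlate_summary_table(kie_systems(), "ddH", "ddS")
#> Error-weighted linear fit (n = 8): slope = 4.428 +/- 0.3883,
#>   intercept = -15.23 +/- 2.839, adj. R^2 = 0.949
```

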