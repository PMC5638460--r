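# hemolig

Quantitative analysis of hemoglobin ligand binding for comparative
physiology, built around the hemoglobin system of the Greenland shark
(*Somniosus microcephalus*) — three closely related isoforms whose oxygen
affinity is strongly modulated by ATP, pH and temperature.

Hemoglobin function in fish is characterised by a standard battery of
measurements, each with its own small model:

* **Spectral unmixing** — absorbance spectra decomposed into nonnegative
  combinations of oxy-, deoxy- and met-Hb references plus a constant
  baseline, giving fractional saturation `Y = oxy / (oxy + deoxy)`.
* **Oxygen equilibrium** — the Hill equation
  `Y = pO2^n / (P50^n + pO2^n)` fitted by nonlinear least squares for the
  half-saturation pressure `P50` (Torr) and cooperativity `nH`.
* **Thermodynamic linkage** — the Bohr coefficient
  `phi = dlog(P50)/dpH` (proton release per tetramer `4|phi|`), the van't
  Hoff oxygenation enthalpy
  `dH = -4.574 * (T1*T2/(T1-T2)) * dlog(P50) / 1000` kcal/mol corrected for
  the heat of O2 solubilisation (−3 kcal/mol), and extrapolation of `P50`
  across temperature and pH along linear van't Hoff and Bohr plots.
* **Flash-photolysis kinetics** — nanosecond CO-rebinding traces modelled
  as two stretched-exponential geminate components plus two exponential
  bimolecular components assigned to the fast-rebinding R and
  slow-rebinding T quaternary states,
  `N(t) = sum_i A_i exp(-(t/tau_i)^beta_i) + A_R exp(-k_R t) + A_T exp(-k_T t)`,
  fitted globally across CO concentrations and effector conditions with
  shared rate constants (`k = kon * [CO]`).
* **Stopped-flow displacement** — O2→CO displacement at 420 nm fitted
  mono-exponentially for the R-state O2 dissociation rate `koff,R`.
* **Autoxidation** — met-fraction time courses from spectral series; `kox`
  (min^-1) as the initial-phase (≤10% conversion) linear slope.

Raw instrument traces for such studies are generally unpublished, so the
package ships a seeded synthetic-data module that generates every input
signal with the statistical structure the analysis assumes, plus the
published parameter sets of the three shark isoforms as generator presets
(`hb_presets()`, `hb_scenario()`). Every estimator is validated by
generator→fitter round trips, Monte-Carlo recovery studies and independent
brute-force oracles.

## Worked example

Fit a simulated 5-step equilibrium curve and run the linkage layer on the
isoform-1 P50 grid:

```r
library(hemolig)

cur <- simulate_equilibrium_curve(P50 = 14.4, n = 1.8, steps = 5,
                                  noise_sd = 0.01, seed = 7)
fit_hill(cur)
#> <hb_hill_fit> P50 = 14.522 +/- 0.232 Torr, nH = 1.721 +/- 0.061 (RSS 0.000504)

pre <- hb_presets()
eq  <- pre$equilibrium[pre$equilibrium$isoform == "Hb1", ]
grid <- hb_p50_grid(temperature_C = eq$temperature_C, pH = eq$pH,
                    atp = eq$atp, P50_torr = eq$P50_torr, isoform = "Hb1")
linkage_summary(grid)
#> <hb_linkage_result> Hb1 (anchor pH 7.4)
#>   stripped phi=-0.299 protons=1.19 dH_corr=-7.92 kcal/mol P50(0 C)=1.02 Torr
#>   atp      phi=-0.722 protons=2.89 dH_corr=-0.69 kcal/mol P50(0 C)=8.14 Torr
```

The simulated curve round-trips its generating parameters within the noise
(P50 14.5 ± 0.2 Torr vs 14.4 generated). For the stripped protein the
corrected oxygenation enthalpy is −7.9 kcal/mol and the 0 °C affinity
extrapolates to P50 ≈ 1.0 Torr — oxygen affinity rises steeply toward polar
water temperatures, and ATP (which stabilises the low-affinity T state)
weakens both the enthalpy and the affinity. Bimolecular rate constants come
from apparent rates and the dissolved CO concentration:

```r
m <- hb_rebinding_model(data.frame(amplitude = 0.08, tau_s = 1e-7, beta = 0.8),
                        A_R = 0.84, k_R = 940, A_T = 0.16, k_T = 240)
bimolecular_constants(m, co_concentration(1, 298.15))
#>    kon_R    kon_T
#> 959183.7 244898.0
```

`run_pipeline(hb_config(seed = 1, isoforms = "Hb1"))` chains all stages on
synthetic data and returns report tables mirroring the equilibrium
(P50/nH/dH/phi/koff/kox) and kinetic (R%/T%/kon) layouts;
`write_report()` serialises them with the reporting rounding rules.

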