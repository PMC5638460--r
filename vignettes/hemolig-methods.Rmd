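---
title: "Models and methods behind hemolig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hemolig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemolig)
```

hemolig implements the quantitative analysis chain used to characterise the
oxygen-binding behaviour of fish hemoglobins — here anchored to the three
isoforms of the Greenland shark, a polar elasmobranch whose Hbs are strongly
modulated by ATP and pH. The chain runs from raw absorbance signals to
thermodynamic and kinetic constants: spectral unmixing into heme species,
Hill fitting of equilibrium curves, Bohr / van't Hoff linkage, flash-photolysis
R/T kinetic decomposition, stopped-flow dissociation rates, and autoxidation
rates. Because the raw instrument traces behind such studies are rarely
deposited, the package pairs every analysis stage with a seeded generator that
produces synthetic data with the same model structure, so the whole pipeline
is testable end to end.

## Spectral decomposition

A measured spectrum is modelled as a nonnegative linear combination of
reference spectra (oxy-, deoxy- and met-Hb) plus a single
wavelength-independent baseline offset:

$$ A(\lambda) \approx \sum_s c_s\, R_s(\lambda) + b, \qquad c_s \ge 0 .$$

The offset is profiled out analytically by mean-centring, after which the
coefficients are the nonnegative least-squares solution (Lawson–Hanson, via
`pracma::lsqnonneg`). Nonnegativity is a physical constraint — species
fractions cannot be negative — and is imposed during the fit rather than by
clipping, which would bias the other coefficients. The default fitting window
is the Soret region, 380–500 nm, where the heme bands are most informative;
it is configurable through the `window` argument of `unmix()`.

Fractional saturation is `oxy / (oxy + deoxy)`. The met coefficient is
reported but excluded from the denominator: ferric heme does not bind oxygen,
and oxidation is treated as a separate correction. The met reference is
included with a free coefficient by default during oxygenation runs; fixing
it is possible by omitting it from the basis. Saturation is invariant under
uniform rescaling of the coefficients, which makes it robust to overall
concentration and pathlength errors.

Unmixing is validated against an exhaustive grid-search oracle (coarse grid
over coefficient space with a local refinement, offset profiled per
candidate) on small instances; the two agree to the oracle's grid resolution.

## Oxygen equilibrium: the Hill fit

Equilibrium curves are fitted with the Hill equation

$$ Y = \frac{p\mathrm{O}_2^{\,n}}{P_{50}^{\,n} + p\mathrm{O}_2^{\,n}} $$

by nonlinear least squares on the untransformed saturation scale
(Levenberg–Marquardt, `minpack.lm`). The classical Hill-plot regression of
$\log[Y/(1-Y)]$ on $\log p\mathrm{O}_2$ is used only to initialise $P_{50}$
and $n$: linearisation distorts the error structure of $Y$, so it is never
the estimator. Bounds are $P_{50} \in (0, 1000]$ Torr and $n \in [0.3, 6]$;
standard errors come from the local curvature of the fit. Curves whose
points all lie on one side of $Y = 0.5$ are fitted but flagged with an
extrapolation warning, since $P_{50}$ is then outside the measured range.

Curves recorded as absorbance steps at 436 nm (a deoxy-sensitive wavelength)
can be converted with `saturation_from_A436()`, which requires the fully
deoxygenated and fully oxygenated endpoint absorbances to anchor the linear
map. Heme concentrations are estimated by Beer–Lambert from the CO-ferrous
bands (mean of 540 and 569 nm, $\varepsilon = 13.4$ mM$^{-1}$cm$^{-1}$) or
the Soret at 405 nm ($\varepsilon = 150$ mM$^{-1}$cm$^{-1}$).

## Thermodynamic linkage

The Bohr coefficient is $\varphi = \Delta\log P_{50} / \Delta\mathrm{pH}$,
computed two-point or, with more pH values, as the OLS slope of the Bohr
plot (declared linear over the pH range examined). Oxygen-linked proton
release per tetramer is $4\,|\varphi|$.

The oxygenation enthalpy uses the integrated van't Hoff relation in its
conventional two-temperature form,

$$ \Delta H = -4.574 \cdot \frac{T_1 T_2}{T_1 - T_2} \cdot
   \frac{\Delta \log P_{50}}{1000} \ \text{kcal mol}^{-1}, $$

with 4.574 ($= R\ln 10$ in cal mol$^{-1}$K$^{-1}$) used exactly as the
conventional constant so that reported digits match the standard
calculation. The heat of O$_2$ solubilisation ($-3$ kcal/mol) is removed to
give the corrected value ($\Delta H_\mathrm{corr} = \Delta H_\mathrm{raw} +
3$); the expression is symmetric under exchange of the two state points.
Sub-zero operating points — relevant for a polar shark but below the
instrument's working range — are obtained by fitting $\log P_{50}$ linearly
against $1/T$ and evaluating at the target temperature, with an optional
Bohr shift $\varphi \cdot \Delta\mathrm{pH}$ to move across pH. Celsius is
converted with 273.15 everywhere; reported values are rounded (one decimal)
only in the report layer.

Note that two-point Bohr coefficients recomputed from rounded P50 values can
differ from coefficients obtained on unrounded data or more pH points (e.g.
5.5 vs 8.9 Torr across 0.7 pH units gives $-0.30$ where $-0.2$ is reported
from the original data); the package always reports what it computes.

## Flash-photolysis kinetics

A nanosecond photolysis trace is modelled as two stretched-exponential
geminate components plus two exponential bimolecular components:

$$ N(t) = \sum_{i=1}^{2} A_i e^{-(t/\tau_i)^{\beta_i}}
        + A_R e^{-k_R t} + A_T e^{-k_T t}. $$

The geminate phase (CO-concentration independent, ns–µs) reflects rebinding
from inside the protein matrix; the bimolecular phase is resolved into
fast-rebinding R-state and slow-rebinding T-state populations, because the
R→T quaternary relaxation overlaps the rebinding reaction in tetrameric
Hbs. The component count is fixed (no model selection); a one-stretched
variant is available via `n_stretched = 1` for low-SNR traces.

Numerical choices:

* Fitting operates on the supplied samples with uniform weights; traces are
  expected log-spaced in time so that all ~eight decades carry comparable
  leverage (standard flash-photolysis practice).
* Lifetimes and rates are fitted on a log10 scale. Bounds separate the
  phases and prevent label swapping: $\tau \in [10^{-9}, 10^{-4}]$ s,
  $\beta \in [0.3, 1]$, apparent bimolecular rates in $[1, 10^6]$ s$^{-1}$.
  R/T identity is enforced by relabelling so $k_R > k_T$.
* Initialisation is deterministic: the geminate block from the early-time
  plateau, the bimolecular pair from a two-exponential fit of the tail
  started from a fixed grid of rate ratios.
* When one fitted bimolecular amplitude falls below 1% of the phase its
  rate is unidentifiable; the dominant component is then reported as R,
  with the stray amplitude kept in the T slot. Single-phase traces are
  therefore read as pure R.

`global_fit()` fits several traces simultaneously with shared rate
parameters: the apparent bimolecular rates are constrained to
$k = k_\mathrm{on} [\mathrm{CO}]$ per trace (Henry's law converts the CO
partial pressure via a solubility table with entries at 15, 20 and 25 °C;
$9.8\times10^{-4}$ M atm$^{-1}$ at 25 °C), while amplitudes are free per
trace — allosteric effectors such as ATP change the R/T partitioning, not
the rate constants. Geminate lifetimes and stretches are shared by default;
`share_geminate = FALSE` shares only the bimolecular constants, since
whether geminate parameters should be pooled across conditions is a genuine
modelling choice. The global fit is initialised from independent per-trace
fits, which in practice removes the local-minimum failures that a single
heuristic start suffers with rate ratios as low as $k_R/k_T \approx 4$.

R/T fractions are the exponential amplitudes normalised by the bimolecular
total, in percent; `bimolecular_constants()` divides apparent rates by
[CO], and the ratio $k_{\mathrm{on},R}/k_{\mathrm{on},T}$ cancels [CO]
exactly. `compare_conditions()` reports R-population changes (points and
relative percent) and rate ratios across conditions.

Identifiability deserves emphasis: with additive noise of 0.01 on $N$, a
*single* trace constrains the R fraction to only about ±3 points (median)
because the two bimolecular rates differ by less than a factor of four. The
pooled global analysis — two CO pressures and the ±ATP pair with shared
rates, which is how such data are actually analysed — brings the median
error below 1 point. The Monte-Carlo tests reflect both readings.

## Displacement and autoxidation

O$_2$→CO displacement traces at 420 nm are fitted as
$A(t) = A_\infty + \Delta A\, e^{-k t}$; `koff` ($=k$) is the R-state O$_2$
dissociation rate because the protein is fully oxygenated (hence R-state) at
the start of the mixing reaction. The constant offset absorbs the endpoint,
making the estimate invariant under affine transformations of the
absorbance axis; a warning is raised when the trace spans fewer than three
lifetimes.

Autoxidation is followed as the met fraction versus time, with fraction 0
anchored by the first post-oxygenation spectrum and fraction 1 by the
ferricyanide-oxidised spectrum; raw spectral series are converted by
two-component unmixing (oxy + met). The rate `kox` (min$^{-1}$) is the OLS
slope of the initial phase, defined as points with at most 10% conversion
(configurable; the definition of "initial" is a choice, recorded in the
output). On a saturating exponential $1 - e^{-kt}$ this window slope
underestimates $k$ by at most ~5–6% (series expansion of $1-e^{-x}$ for
$x \le 0.105$), shrinking as the window does — the estimator is tested at
windows 0.10, 0.05 and 0.02.

## The synthetic-data generators

Each generator emulates one signal type with the model structure the
analysis assumes, and every one is a pure function of its arguments
including the seed (the caller's RNG stream is restored on exit):

* equilibrium curves: 5 saturation steps evenly spaced in $Y \in [0.2, 0.8]$
  (4–6 steps in the ~20–80% range is the experimental practice), pO$_2$
  solved from the inverse Hill equation, Gaussian noise (sd 0.01) on $Y$
  only;
* photolysis traces: the rebinding model on a log-spaced grid from 10 ns to
  1 s at 25 points per decade (a typical log-averaged trace density),
  additive Gaussian noise (sd 0.01) on $N$;
* displacement traces: mono-exponential decay with noise sd 0.5% of a
  0.1 AU amplitude;
* autoxidation: $1 - e^{-k_\mathrm{ox} t}$ sampled every 30 min over 20 h,
  optionally rendered as raw oxy/met mixture spectra;
* reference spectra: Gaussian-band synthetic stand-ins on a 1-nm grid with
  the met Soret near 405 nm, the oxy Soret near 415 nm and a deoxy band
  near 430 nm — adequate for exercising the unmixing machinery, not a model
  of real heme band shapes.

The bundled presets (`hb_presets()`, `hb_scenario()`) carry the published
equilibrium and kinetic parameter sets of the three isoforms verbatim as
generator inputs, so a synthetic analogue of each results table can be
regenerated and compared. No geminate parameters are published for these
Hbs; the defaults (total geminate amplitude 8% of the signal, lifetimes
100 ns and 1 µs, $\beta = 0.8$) are declared assumptions consistent with the
described "small-amplitude" geminate phase. Noise is additive Gaussian and
homoscedastic per signal type — real instrument noise is neither exactly
Gaussian nor homoscedastic, and real spectra have correlated baselines, so
passing tests demonstrate correctness of the estimators under the stated
model, not robustness to every instrument artefact.

## Pipeline, problem sizes and limitations

`run_pipeline()` chains the stages for selected isoforms — equilibrium
curves through Hill and linkage, trace pairs through the global kinetic
fit, displacement and autoxidation through their estimators — deterministic
given the config and master seed (stage seeds are derived arithmetically).
Reports round only at serialisation: one decimal for P50/nH/enthalpy/Bohr
columns, two significant figures for rates.

The validation suite uses problem sizes chosen to make the statistics
meaningful while staying quick to run: 200 Monte-Carlo replicates for the
Hill and displacement estimators, 100 pooled global fits for the R/T
fractions, 5 oracle comparisons for unmixing.

Known limitations: no Adair/MWC equilibrium models and no Wyman linkage
beyond the linear Bohr and van't Hoff forms; no master-equation modelling of
the quaternary relaxation, no transient-spectra SVD, and no
instrument-response deconvolution; no mechanistic (pH-dependent) autoxidation
rate law; Torr↔molar oxygen-solubility conversion is out of scope. The urea
comparison reuses the equilibrium machinery unchanged (urea enters only as
condition metadata), and `compare_conditions()` implements the arithmetic of
R-population changes only.
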