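---
title: "Crystallization kinetics of amorphous drugs: models, simulators and fitting choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Crystallization kinetics of amorphous drugs: models, simulators and fitting choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amorphkin)
```

## The problem

Amorphous (glassy) forms of poorly soluble drugs dissolve faster than their
crystals but are physically unstable: nuclei formed during storage — even far
below the glass transition — can trigger cold crystallization on heating and
shorten the shelf life of the amorphous advantage. Quantifying that risk from
calorimetric and diffraction data involves a chain of analyses that are
usually performed ad hoc in spreadsheets. `amorphkin` packages that chain:
thermogram feature extraction, isothermal Avrami kinetics, isoconversional
(KAS) kinetics with frequency-factor extraction and ANCOVA, split
pseudo-Voigt profile fitting for polymorph ratios, and the small closed-form
thermodynamic computations around them. A synthetic-data generator emulates
the full experimental design so every stage is testable end to end without
instrument data. Default parameter values throughout describe amorphous
terfenadine (TFD), a class III glass former with two monotropically related
polymorphs (form I melting near 150 °C, form II near 146 °C).

## Models

### Nonisothermal cold crystallization

The simulator's exotherm follows an effective Arrhenius/Avrami–Erofeev rate
law for the crystallized fraction $\alpha$,

$$\frac{d\alpha}{dt} = A e^{-E_a/RT}\, n (1-\alpha)\,
  [-\ln(1-\alpha)]^{(n-1)/n},$$

integrated along the temperature program. Substituting
$u = [-\ln(1-\alpha)]^{1/n}$ gives $du/dt = A e^{-E_a/RT}$, so the
conversion has the closed form
$\alpha(t) = 1 - \exp\{-[u_0 + \int_0^t k(T(s))\,ds]^n\}$ and only a single
quadrature of the rate constant is needed. We use this exact solution on a
fine trapezoidal grid rather than an adaptive ODE stepper: it is faster,
has no stiffness issues near complete conversion, and the test suite
cross-checks it against `deSolve::lsoda` on the raw rate law (agreement
better than $10^{-3}$ in sup-norm). The seed $u_0$ comes from
$\max(\alpha_0, 10^{-8})$ because the rate vanishes at exactly
$\alpha = 0$; `alpha0` is the simulator's handle for preformed crystal
nuclei. There is no quantitative model linking an annealing temperature and
duration to a nucleus density, so mapping storage conditions to `alpha0` is
deliberately left to the user.

The heat-flow trace (mW/mg, exo up) superposes (i) the sensible-heat
baseline $-c_p(T)\beta/60$ with a sigmoidal heat-capacity step of height
$\Delta c_p$ at $T_g$, (ii) the exotherm $\Delta H_c\, \dot\alpha/60$, and
(iii) two melting endotherms modeled as split pseudo-Voigt peaks in
temperature. Endotherm mixing defaults to 0 (split-Gaussian): Lorentzian
tails truncated at finite integration limits would silently violate energy
bookkeeping, which the tests enforce to 0.1 %. Enthalpy-relaxation
overshoot at $T_g$ is not simulated.

Default kinetics place the simulated events where the measured ones sit.
For the sub-$T_g$-annealed condition, $E_a = 134$ kJ/mol and $n = 4.7$ are
the measured values; $\ln A = 39.6$ (in $\ln(1/\mathrm{min})$) was
back-solved once from the KAS equation so that the extrapolated onset at
1 °C/min falls at ≈107.4 °C. For the room-temperature-annealed condition
($E_a = 115$ kJ/mol, $n = 4.1$), $\ln A = 32.77$ was calibrated the same
way against its onset of 113.7 °C. Note that these $\ln A$ values are far
below the ≈56–63 obtained by inverting reported KAS intercepts with the
Avrami–Erofeev model; no unit convention we examined reconciles intercepts
of ≈47–54 with the KAS equation evaluated at the observed onset
temperatures (the synthetic intercepts come out near 30). The package
therefore validates the frequency-factor *identity*
(`frequency_factor()`, exact algebra) and the *accuracy* of the KAS chain
(synthetic round trip) separately, and makes no claim about absolute
intercept magnitudes.

### Protocol caveat: where the ramp starts

Isoconversional theory assumes the Arrhenius temperature integral
accumulates from temperatures where the rate is negligible. Starting the
analyzed ramp only ~20 °C below the event (e.g. a fast pre-ramp to 80 °C
followed by the slow ramp) truncates that integral unevenly across heating
rates and biases the recovered $E_a$ by about +4 % under the default
kinetics. The simulator, tests and demo pipeline therefore use full ramps
from 25 °C, where the round-trip recovery is 0.1 % on $E_a$. Users
analyzing real pre-ramped data should expect this protocol bias.

### Thermogram features

* **Glass transition** — apparent heat capacity $c_p = -60\,HF/\beta$ is
  fitted with a logistic step on a linear baseline; $T_g$ is the
  half-height midpoint, $\Delta c_p$ the step height. A step below three
  times the residual noise returns a not-found result rather than an error.
* **Onset** — the standard extrapolated onset: intersection of the
  pre-peak baseline with the tangent at the leading-edge inflection, the
  derivative taken from a smoothing spline for noise stability.
* **Event enthalpies** — trapezoidal integration over a linear baseline
  anchored in short edge windows at the user-set limits; sigmoidal
  baselines are out of scope. Enthalpies are reported positive with the
  event sign attached.
* **Conversion curves** — partial-area construction with endpoints exactly
  0 and 1. Baseline round-off can produce increments of order $-10^{-9}$;
  the inverse interpolation for isoconversional analysis keeps only
  strictly increasing points.
* **Melting doublet** — separated by model fitting (two split pseudo-Voigt
  peaks plus linear baseline), not by a perpendicular drop; how the
  reference values were split is unknowable from the printed tables, and
  model fitting is the choice that generalizes to stronger overlap. Peaks
  are reported ordered by center (lower = form II), so input order never
  matters. A vanishing form I area yields an infinite-ratio flag.

### Isothermal kinetics (modified Avrami)

Reversing heat capacity decays from the amorphous to the crystalline
plateau as the sample crystallizes. The amorphous fraction

$$f(t) = \frac{C_p(t) - C_p^{cryst}}{C_p^{amorph} - C_p^{cryst}} \times 100$$

uses plateau means of the first and last 100 samples (`edge_count`). $f$ is
*not* clipped to [0, 100]: clipping noisy excursions would bias the fit.
The modified Avrami model $f(t) = 100 \cdot 0.9^{(t/t_{10})^n}$ is fitted
by bounded Levenberg–Marquardt with a multistart over $n \in \{1,\dots,6\}$
and $t_{10}$ initialized at the observed 90 % crossing; this supersedes the
spreadsheet-solver fits common in this field. The plateau-definition
windows are excluded from the fitted range so the segments that define the
endpoints are not also fitted — whether to do so is genuinely open; we
exclude them because they carry no shape information and their residuals
are pure noise. Traces whose $f$ never leaves the 80–30 % band are flagged
degenerate instead of fitted. Note the plateau means are only estimates of
the true plateau heat capacities; with coarse sampling the early-decay
points contaminate the amorphous plateau slightly, which is why the
round-trip tests sample at 0.05 min.

### Isoconversional (KAS) analysis

$$\ln\frac{\beta}{T_\alpha^2} = -\frac{E_a}{R T_\alpha}
 + \ln\frac{A R}{E_a\, g(\alpha)}, \qquad
 g(\alpha) = [-\ln(1-\alpha)]^{1/n}$$

with $\beta$ in K/min, $T$ in K, $E_a$ in J/mol, $A$ in 1/min. Ordinary
least squares per conversion level across at least three heating rates;
$E_a = -R\,\mathrm{slope}$; standard errors are the regression standard
errors. The frequency factor inverts the intercept with the
Avrami–Erofeev $g(\alpha)$, taking $n$ from the isothermal fit of the
matching condition (the 40-day fits by default in the demo). The full
conversion grid is computed, but interpretation conventionally focuses on
$\alpha \le 0.10$, where single-step kinetics is the better approximation;
a falling $E_a(\alpha)$ profile signals multistep kinetics, and the test
suite reproduces that signature with a two-process mixture. ANCOVA
between conditions is implemented as nested F-tests: the slope p-value
from the rate-by-group interaction in the full model, the intercept
p-value from the group effect under a common slope — the standard
construction. Identical groups with zero residual return `NA` p-values
with a `zero_residual` flag.

### Powder profiles

The split pseudo-Voigt (Toraya-style convention) gives each side of a peak
its own FWHM and Gaussian–Lorentzian mixing, both components unit-height
so the profile is continuous at the center. Peak areas use the analytic
half-Gaussian/half-Lorentzian side-area formula

$$\mathrm{area} = \frac{A}{2}\sum_{s \in \{L,R\}}
 \left[\eta_s \frac{\pi w_s}{2} +
 (1-\eta_s)\, w_s \sqrt{\frac{\pi}{4\ln 2}}\right],$$

never numerical integration of the fit. Profiles plus a polynomial
background (degree 3 by default; the exact background model is a free
choice) are fitted simultaneously by bounded least squares. Normalized
areas divide by the reference reflection at 2θ = 16.1° and scale by 1000,
so the reference row is exactly 1000. Vendor implementations of the
"split pseudo-Voigt" differ; the convention above is fixed and documented
here.

### Closed forms

`entropy_of_fusion()` ($\Delta S_f = \Delta H_f/T_m$),
`critical_radius()` ($r^* = 2\sigma T_m / [\Delta H_f (T_m - T)]$,
accepting constant or temperature-dependent $\sigma$), and
`correct_concentration()` (rescaling a dissolution trace so its first
point equals the nominal pre-loaded concentration). The critical radius
needs a *volumetric* enthalpy of fusion to return meters;
`molar_to_volumetric_enthalpy()` converts given a molar volume. No
interfacial energy or molar volume for TFD is established, so $r^*$
outputs are illustrative — the package makes no claim of matching a
measured nucleus size.

## What the generator emulates — and what it does not

The generator reproduces the *structure* the analyses assume: a sigmoidal
$c_p$ step, an Avrami–Erofeev exotherm whose position shifts with heating
rate and nucleus seed, an overlapping melting doublet with configurable
area ratio, plateau-to-plateau reversing-heat-capacity decays, peaks on
smooth backgrounds, and a supersaturation pulse with a first-point
calibration bias. Noise is additive iid Gaussian with explicit seeds
(identical seeds give bit-identical traces). Real data differ in ways the
generator ignores: enthalpy-recovery overshoot at $T_g$, baseline
curvature and drift, heat-capacity change across crystallization,
crack-formation spikes, instrument smearing, heteroscedastic counting
noise in diffraction, and run-to-run mass uncertainty. Passing round-trip
tests therefore demonstrates correctness of the estimators under the
stated model, not robustness to every instrumental artifact.

## Problem sizes and numerical choices

Simulated thermograms use a 0.02 min time step (≈6 800 points per ramp at
1 °C/min); the demo pipeline uses 0.05 min. Isothermal traces sample at
0.05–0.1 min over 3–4 × $t_{10}$. Quadrature is trapezoidal throughout;
energy bookkeeping holds to 0.1 %. The ANCOVA null calibration uses 1 000
replicates of a 2 × 5-point design. The two-condition demo pipeline
(three heating rates each, dt = 0.05 min) completes in a few seconds on
one CPU and is bit-reproducible: every random draw derives from the config
seed through fixed substream offsets, and the manifest hash covers the
four output tables.

## Worked demo

```{r demo, eval = FALSE}
res <- run_pipeline(out_dir = "results")
res$avrami
res$kas[res$kas$alpha %in% c(0.05, 0.10), ]
plot_ea_profile(res$kas)
```

## Known limitations

* Single-event windows must be supplied by the user; there is no automatic
  segmentation of arbitrary thermograms.
* The linear event baseline is the only option; strongly curved baselines
  will bias enthalpies.
* Only the KAS isoconversional estimator is provided (no Friedman,
  Ozawa–Flynn–Wall or nonlinear Vyazovkin variants), and only the
  Avrami–Erofeev reaction model for frequency-factor extraction.
* The dissolution model is a phenomenological pulse; it encodes shape, not
  precipitation physics, and the hydrate formation seen in real
  supersaturation experiments is outside its scope.
* Raw modulated-DSC deconvolution is not implemented; the package starts
  from the reversing heat capacity.
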