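---
title: "Linking picosecond water dynamics to enzyme activity: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking picosecond water dynamics to enzyme activity: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thzhyd)
```

## The scientific question and the two measurement arms

Neutral osmolytes — urea, polyols, sugars — change the activity of α-amylase
without touching its charge state or pH. `thzhyd` implements the analysis
that attributes this effect to the *water*: osmolytes alter the picosecond
collective dynamics of the hydrogen-bond network, and the enzyme's reaction
rate tracks that alteration.

Two independent measurements are combined:

* **Dielectric arm.** Terahertz time-domain spectroscopy yields the complex
  permittivity of the solution in the reliable band 0.3–2.5 THz. The loss
  spectrum ε″(ν) carries the hydration signal.
* **Kinetics arm.** α-Amylase cleaves amylose; iodine trapped in the amylose
  helix absorbs at 615 nm, so cleavage bleaches the solution. The absorbance
  decay gives a first-order rate constant per run.

## The dielectric model and its conventions

The water response is modeled as two Debye relaxations plus a damped harmonic
oscillator for the intermolecular stretch, scaled by the water volume
fraction *c*:

$$\varepsilon(\nu) = c\left(\frac{\Delta\varepsilon_{slow}}{1 + i\,2\pi\nu\tau_{slow}}
  + \frac{\Delta\varepsilon_{fast}}{1 + i\,2\pi\nu\tau_{fast}}
  + \frac{A_s}{\nu_s^2 - \nu^2 + i\,\nu\gamma_s}\right)$$

Parameters, units and defaults:

| parameter | meaning | unit | default | role in fits |
|---|---|---|---|---|
| Δε_slow | collective-reorientation amplitude | — | 73.8 (water) | free |
| Δε_fast | freed-molecule amplitude | — | 1.85 (water) | free |
| τ_slow | slow relaxation time | ps | 9.20 | fixed |
| τ_fast | fast relaxation time | ps | 0.245 | fixed |
| A_s | stretch amplitude | THz² | 35.0 | free for water, fixed for solutions; swept 33–37 for error bars |
| ν_s | stretch resonance | THz | 5.30 | fixed |
| γ_s | stretch damping | THz | 32.5 | fixed |
| c | water volume fraction | — | from density | fixed per sample |

Two conventions matter and are easy to get wrong:

* **Units.** The Debye denominators use the dimensionless product
  2πν[THz]·τ[ps]; the oscillator term uses plain ν in THz. This convention
  reproduces a physically sensible pure-water loss (≈ 2.76 at 1 THz) with
  the parameters above; treating the oscillator frequency as angular instead
  would push the resonance far outside the observed band.
* **Sign.** `eval_dielectric()` returns ε = ε′ + iε″ with ε″ ≥ 0
  (loss-positive), i.e. the conjugate of a literal transcription of the
  denominators above.

Only ε″ is ever fitted. The real part barely responds to hydration and is
noisier, and since the model has no ε∞ offset a real constant would be
unidentifiable anyway. Osmolyte self-absorption is neglected: at 0.75 mol/L
the solutes absorb far less THz radiation than water.

## Spectral fitting

`fit_pure_water()` frees {Δε_slow, Δε_fast, A_s}; `fit_solution()` frees only
the two relaxation amplitudes with A_s fixed (default 35.0 THz²) and *c*
supplied from the composition. Both use bounded Levenberg–Marquardt on
uniform-weight ε″ residuals restricted to the fit band, with a cost tolerance
of 1e-10 and at most 1000 iterations; non-convergence sets a flag that
downstream stages refuse to consume. Amplitudes are bounded below by zero —
physical — and above by ten times the water values, purely to stabilize the
optimizer on pathological inputs; the upper bound deliberately does *not*
clip urea-like solutions whose slow amplitude exceeds the water value.
Start values are the pure-water amplitudes, which are already close for any
realistic sample.

Because ε″ is linear in the free amplitudes, the least-squares problem has a
unique minimum; the test suite verifies the optimizer against a profiled
dense grid search (each amplitude scanned at 0.01 resolution with the other
minimized in closed form). A plain two-dimensional grid argmin is *not* used
as the oracle: the two amplitude bases are strongly correlated over the band,
so the discrete argmin can slide several grid steps along the flat valley of
the SSE surface while representing the same minimum.

One linearity caveat: declaring the same spectrum at c and c/2 doubles the
fitted amplitudes *exactly* only when the fixed stretch contribution is zero,
because the model scales A_s by c while the fit holds A_s fixed. The tests
assert the exact identity in a stretch-free configuration and the approximate
version is left undocumented as an invariant.

## From amplitudes to hydration

The composition of each solution enters through mass balance. With molarity
C, solution density ρ and solute molar mass M_s, the water mass per litre is
m_w = 1000·ρ − C·M_s, the volume fraction is c = (m_w/ρ_water)/1000 with
ρ_water = 0.9975 g/mL at 23 °C (the density-measurement temperature,
configurable), and α = (m_w/M_w)/C waters per osmolyte.

The hydration fraction applies Kirkwood correlation factors 2.9 (slow) and
1.0 (fast):

$$a_{hyd} = \frac{(\Delta\varepsilon_{slow}^{w} - \Delta\varepsilon_{slow}^{s})/2.9
  - (\Delta\varepsilon_{fast}^{s} - \Delta\varepsilon_{fast}^{w})/1.0}
  {\Delta\varepsilon_{slow}^{w}/2.9 + \Delta\varepsilon_{fast}^{w}/1.0},
  \qquad n_{hyd} = \alpha \, a_{hyd}.$$

The fast factor of 1.0 is implemented as an explicit division for
auditability. A *gain* in the fast mode (solute-isolated water molecules)
subtracts from the hydration estimate, and a slow amplitude above the water
value yields negative a_hyd — the structure-breaking, water-accelerating
signature of urea. For ternary amylase/osmolyte/water systems only a_hyd is
reported, never n_hyd: with two solutes a per-osmolyte water count is not
meaningful.

Uncertainty from the fixed stretch amplitude is quantified by
`hydration_sweep()`: both the water reference and the solution are refit at
each A_s in {33, 35, 37} THz² and the min/max over the sweep become the
bounds around the central (35.0) value.

## Kinetics and bottle pairing

`fit_decay()` fits Abs(t) = B + A0·exp(−kt) by bounded least squares after
discarding the first 15 s (stirring transients) and re-originating time at
the first retained sample, so A0 + B is the absorbance at the trim point.
The time origin choice only rescales A0; k is unaffected. Rising traces are
flagged as non-decays rather than fitted.

Amylose concentration differs between sample bottles (filtration during
preparation), which multiplies every rate from a bottle by an unknown
factor. `normalize_rates()` divides each osmolyte run's k by the mean k of
the water controls *from the same bottle*; the factor cancels exactly, which
the tests assert with planted multiplicative bottle effects. Runs without a
same-bottle water control are excluded with a warning and reported. Error
bars are sample (n−1) standard deviations over replicate ratios.

## Correlation

`linear_fit()` is unweighted ordinary least squares of k/k_water on n_hyd
(or a_hyd), with R² = 1 − SS_res/SS_tot. The displayed error bars do not
weight the fit; they are carried for reporting. `correlation_report()` joins
the binary and ternary fits and flags sign consistency — both slopes
negative means water-binding osmolytes suppress activity in both system
types.

## What the synthetic generator emulates — and what it does not

`gen_study()` replaces the instrument. Its defaults define the simulated
study conditions:

* Seven osmolytes at 0.75 mol/L — urea, propylene glycol, diethylene glycol,
  glycerol, fructose, sucrose, trehalose — with planted hydration numbers
  −3, 0.5, 1.5, 2.5, 4, 5.5, 7, spanning structure breaking to strong
  binding. Densities are realistic values for 0.75 M aqueous solutions at
  23 °C; they are synthetic stand-ins, not measured data.
* A linear activity law k/k_water = 1.0 − 0.04·n_hyd, chosen so the ratio
  spans roughly 1.12 (urea) down to 0.72 (trehalose) — the magnitude range a
  strong osmolyte effect produces.
* Five amylose bottles with multiplicative factors uniform in [0.7, 1.3] and
  three replicates per condition.
* Noise: additive Gaussian σ = 0.02 on ε″ (instrument-like), additive
  Gaussian σ = 0.005 on absorbance, and multiplicative lognormal rate noise
  (sdlog 0.02) for run-to-run variability.

Solution spectra are planted by inverting the hydration formula: the slow
amplitude is chosen so the noiseless pipeline recovers the target n_hyd
exactly, with the fast amplitude held at the water value. Decay schedules are
5 s sampling for 10 min including pre-trim samples, so the trim path is
always exercised. Everything is seeded and byte-reproducible.

What the generator does **not** emulate: correlated (non-white) spectral
noise, temperature drift, day-dependence of the amylose substrate, deviations
from first-order kinetics, osmolyte THz absorption, and fast-amplitude
changes uncorrelated with the slow mode. Passing recovery tests therefore
demonstrate the *analysis* is correct and unbiased under the stated noise
model — they do not validate the physical model against a real instrument.

## Numerical choices and degenerate inputs

* Fit band restriction happens before residual computation; out-of-band
  points in an input file cannot influence a fit.
* Fewer than 10 in-band spectral points, traces shorter than 60 s past the
  trim, or fewer than 10 retained samples are hard errors.
* All-equal x in the correlation is a degenerate-fit error; fewer than three
  points is rejected at construction.
* Pure water has no α; requesting waters-per-osmolyte at zero molarity is an
  error, and an implausible molarity/density pair (non-positive water mass)
  is rejected at construction.
* JSON results are written with stable key order and full precision, so
  repeated runs on identical inputs are byte-identical.

## Interface choice

The package's surface is its exported functions plus the study-level
`run_pipeline()`; file exchange uses plain CSV (spectra, traces, manifests)
and JSON (results). No shell executable is shipped: the intended users work
in R, and a script wrapping `run_pipeline()` is a one-liner where needed.

## Problem sizes used in the shipped checks

The test suite and the reproduction script use: 45-point spectra
(0.3–2.5 THz at 0.05 THz), 50 noisy spectral replicates for the amplitude
round trip, 200 noisy decays for the rate estimator, 10 instances for the
grid-search comparison, and 100 simulated studies for the slope-recovery
interval. These sizes give Monte-Carlo standard errors comfortably below the
asserted tolerances while keeping a full run under a minute.

## Known limitations

* The Kirkwood factors and all fixed spectral constants are literature
  values at 20 °C; no temperature dependence is modeled.
* The mass-balance volume fraction assumes additive masses and a fixed
  pure-water reference density; partial molar volume effects are ignored.
* Hydration numbers lump strongly and weakly bound water; no per-site
  decomposition is attempted.
* The correlation is descriptive OLS — no errors-in-variables treatment,
  although x-error half-widths from the A_s sweep are reported.
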