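# thzhyd

Do osmolytes change enzyme activity by acting on the enzyme, or by acting on
the *water*? `thzhyd` implements the analysis that answers this for
α-amylase: it links the picosecond collective dynamics of water, measured as
terahertz (0.3–2.5 THz) dielectric loss spectra of osmolyte solutions, to the
enzyme's reaction rate measured through iodine–starch bleaching kinetics. The
package is aimed at biophysical chemists who run THz time-domain spectroscopy
on aqueous samples alongside simple visible-light kinetics, and at anyone who
wants a fully testable, simulation-backed version of that workflow.

## The model

**Dielectric arm.** The loss spectrum of an aqueous sample in the THz band is
modeled as two Debye relaxations plus one damped harmonic oscillator, all
scaled by the water volume fraction *c*:

```
ε(ν) = c [ Δε_slow / (1 + i·2πν·τ_slow)
         + Δε_fast / (1 + i·2πν·τ_fast)
         + A_s / (ν_s² − ν² + i·ν·γ_s) ]
```

with ν in THz and τ in ps. The slow mode (τ_slow = 9.20 ps) is the collective
reorientation of hydrogen-bonded water; the fast mode (τ_fast = 0.245 ps) is
water transiently freed from the network; the oscillator (ν_s = 5.30 THz,
γ_s = 32.5 THz, A_s = 35.0 THz²) is the intermolecular stretch. Fitting holds
all of these fixed and frees only the two amplitudes (plus A_s for the
pure-water reference), over ε″ in 0.3–2.5 THz.

**Hydration.** Amplitude changes between water and solution convert to the
fraction of dynamically altered water via Kirkwood correlation factors
(2.9 slow, 1.0 fast):

```
a_hyd = [ (Δε_slow^w − Δε_slow^s)/2.9 − (Δε_fast^s − Δε_fast^w)/1.0 ]
        / [ Δε_slow^w/2.9 + Δε_fast^w/1.0 ]
n_hyd = α · a_hyd
```

where α is the number of water molecules per osmolyte molecule, obtained from
the solution density by mass balance. Positive n_hyd counts waters bound per
osmolyte; negative n_hyd (urea) means accelerated, structure-broken water.

**Kinetics arm.** Amylose–iodine bleaching at 615 nm follows a first-order
decay `Abs(t) = B + A0·exp(−kt)` (5 s sampling, 10 min, first 15 s trimmed).
Because amylose concentration varies between sample bottles, each rate is
normalized by the pure-water rate *from the same bottle*, `k/k_water`.

**Correlation.** An ordinary least-squares line relates n_hyd (binary
osmolyte/water systems) or a_hyd (ternary amylase/osmolyte systems) to the
mean `k/k_water` per osmolyte.

## Worked example

A complete synthetic study — seven osmolytes at 0.75 mol/L, five amylose
bottles, three replicates, with a planted activity law
`k/k_water = 1.0 − 0.04·n_hyd` — analyzed end to end:

```r
library(thzhyd)

study   <- gen_study(study_design(), seed = 7)
summary <- run_pipeline(study)

summary$binary_fit
#> <correlation_result> n_hyd: slope=-0.03879 intercept=0.9851 R^2=0.99 n=7

head(summary$hydration[, c("osmolyte", "n_hyd", "n_hyd_lo", "n_hyd_hi")], 3)
#>   osmolyte      n_hyd   n_hyd_lo   n_hyd_hi
#> 1     urea -3.2995359 -3.3671273 -3.2319445
#> 2       pg  0.3318752  0.2655475  0.3982029
#> 3      deg  1.4425439  1.3774449  1.5076429

summary$rates[summary$rates$osmolyte %in% c("urea", "trehalose"), ]
#>    osmolyte mean_ratio   sd_ratio n_runs
#> 6 trehalose  0.7219462 0.01421758     15
#> 7      urea  1.1124686 0.02268548     15
```

Reading the output: the recovered correlation slope (−0.039) is close to the
planted −0.04 despite spectral noise (σ = 0.02 on ε″), absorbance noise
(σ = 0.005) and run-to-run rate variability. Urea, whose planted hydration
number is negative (water-structure breaking), *accelerates* the enzyme
(`k/k_water` ≈ 1.11); trehalose, which binds ~7 waters per molecule, slows it
(≈ 0.72). The `n_hyd_lo/hi` bounds come from refitting with the stretch
amplitude swept from 33 to 37 THz².

Individual stages are exported too: `fit_pure_water()`, `fit_solution()`,
`hydration_sweep()`, `fit_decay()`, `normalize_rates()`, `linear_fit()`, and
CSV/JSON readers and writers (`read_spectrum()`, `read_traces()`,
`write_result()`).

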