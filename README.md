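# circatrack

Quantitative single-cell circadian analysis under temperature-cycle
entrainment.

Peripheral circadian oscillators — fibroblasts, dissociated SCN neurons —
keep cell-autonomous clocks with free-running periods scattered around
24 h. Square-wave temperature cycles (*T-cycles*: T20 = 10 h cold / 10 h
warm, T24 = 12 h / 12 h) act as a zeitgeber that can entrain them, pulling
periods toward the cycle length and clustering phases around the cold
phase. `circatrack` is for chronobiologists analyzing long-term
single-cell bioluminescence reporter recordings (e.g. PER2::LUC) under
such protocols: it turns image stacks or per-cell intensity tables into
periods, circadian phases, single-stimulus phase shifts, phase-response
and amplitude-response curves, and circular statistics.

## What it computes

* **Rhythms.** Per cell and stage (Before / During / After the cycles),
  least-squares fits of `f(t) = a·cos(2πt/τ − θ) + offset`, seeded from
  the FFT, with only circadian periods (18 ≤ τ ≤ 30 h) accepted; During
  fits use the last three cycles. Summaries report mean, SD and CV of τ;
  relative amplitude is `a / mean(raw)`.
* **Phases.** Peaks from an 11-h running-average smoothing plus local
  parabola fits; circadian time with CT12 anchored at the end of the cold
  phase (entrained) or rescaled by the cell's own period with the reporter
  peak at CT18 (free run); phase shifts as (expected − actual peak)·24/τ,
  delays negative.
* **PRC/ARC.** Shifts grouped by stimulus-onset CT (delays in [CT6,
  CT18)), group means ± SEM with a two-sample t-test, a display-level
  4th-order polynomial, and amplitude fold changes.
* **Circular statistics.** Mean direction and resultant length, Rayleigh
  uniformity test (Z = n·R̄²), Watson–Williams two-sample test.
* **Imaging.** Kalman-type temporal denoising, median impulse removal,
  globally optimal dynamic-programming spot tracking, windowed trace
  extraction, viability QC.
* **Synthetic data.** A ground-truthed generator — coupled stochastic
  Poincaré oscillators under square-wave thermal forcing plus a
  bioluminescence movie renderer — used to validate every step of the
  chain.

## Worked example

Twenty synthetic fibroblast-like cells, six T20 cycles starting at 72 h:

```r
library(circatrack)

t20 <- temperature_protocol(20, 10, 4, 6, 72)
t20
#> T20 temperature protocol: 6 x (10 h @ 33 degC cold, 10 h @ 37 degC warm)
#>   During: [72, 192) h; constant 37 degC outside

run <- run_pipeline(demo_config("t20", seed = 1))
run$period_summary
#> # A tibble: 3 × 6
#>   stage      n mean_tau sd_tau cv_pct reliable
#>   <fct>  <int>    <dbl>  <dbl>  <dbl> <lgl>
#> 1 Before    20     24.2 1.38    5.72  TRUE
#> 2 During    20     20.0 0.0219  0.110 TRUE
#> 3 After     20     24.5 1.45    5.91  TRUE

run$circ
#> # A tibble: 3 × 8
#>   stage      n  r_bar mean_angle_rad mean_ct       Z        p reliable
#>   <fct>  <int>  <dbl>          <dbl>   <dbl>   <dbl>    <dbl> <lgl>
#> 1 Before    20 0.0607           3.74   14.3   0.0737 9.31e- 1 TRUE
#> 2 During    20 0.996            5.31   20.3  19.9    2.32e-14 TRUE
#> 3 After     20 0.225            1.94    7.42  1.02   3.66e- 1 TRUE
```

Reading this: the population free-runs near 24 h with ~6% period scatter,
adopts the 20-h zeitgeber period during the cycles (CV collapses to
~0.1%), and relaxes back after release. Phases are uniform before
(Rayleigh Z ≈ 0.07, p ≈ 0.93) and tightly clustered during entrainment
(Z ≈ 19.9 of a possible 20, p < 10⁻¹³). `plot_traces()`,
`plot_polar_phases()`, `autoplot()` on fits and PRCs, and broom-style
`tidy()`/`glance()` methods cover inspection; `run_pipeline(cfg, out_dir =
...)` writes tidy CSVs plus a JSON run log, reproducible byte-for-byte for
a given seed. A thin command-line wrapper lives in
`inst/scripts/circatrack.R` (`simulate | run | demo-t20 | demo-t24`).

The methods vignette (`vignettes/circatrack-methods.Rmd`) documents the
models, parameter defaults, numerical conventions, and what the synthetic
generator does and does not emulate.

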