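---
title: "Methods: single-cell circadian analysis under temperature cycles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-cell circadian analysis under temperature cycles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circatrack)
library(dplyr)
```

## The problem

Peripheral circadian oscillators — fibroblasts, dissociated SCN neurons —
carry cell-autonomous clocks with intrinsic free-running periods scattered
around 24 h. Temperature cycles are a physiological zeitgeber for these
cells: a square-wave alternation between a cold and a warm phase (a
*T-cycle*; T20 = 10 h cold + 10 h warm, T24 = 12 h + 12 h) can entrain
them, pulling the expressed period toward T and clustering their phases
around a fixed relationship with the cold phase. `circatrack` implements
the full quantitative chain for such experiments on single-cell
bioluminescence reporter recordings (e.g. PER2::LUC):

1. **imaging** — turn a time-lapse image stack into per-cell intensity
   traces (temporal denoising, impulse-noise removal, spot tracking,
   windowed extraction, viability QC);
2. **preprocessing** — normalization, background subtraction,
   running-average detrending, stage labelling (Before / During / After the
   cycles);
3. **rhythm estimation** — FFT-seeded nonlinear least-squares cosine fits
   per stage, a circadian period filter, relative amplitudes, CV summaries;
4. **phase analysis** — parabolic peak picking, circadian-time conversion,
   expected-vs-observed phase shifts, entrainment filtering,
   phase-response (PRC) and amplitude-response (ARC) assembly;
5. **circular statistics** — mean direction, Rayleigh uniformity test,
   Watson–Williams two-sample test;
6. **synthetic data** — a ground-truthed generator (stochastic Poincaré
   oscillators plus a movie renderer) that stands in for recordings, since
   every step of the chain is validated against it.

## The cosine model

Periods and amplitudes come from least-squares fits of

$$ f(t) = a \cos\!\left(\frac{2\pi t}{\tau} - \theta\right) + \text{offset} $$

to the processed trace of each stage, with $a$ in gray levels, $\tau$ in
hours, and $\theta$, offset shifting the curve along the axes. Note the
phase argument is $2\pi t/\tau$: this is the only form in which $\tau$ is a
period in hours, and the package uses it throughout. Initial values come
from the discrete Fourier transform: $\tau_0$ is the inverse frequency of
the largest periodogram ordinate in the circadian band (periods 18–30 h),
$a_0$ and $\theta_0$ from the complex coefficient there, the offset from
the segment mean. The nonlinear refinement is Levenberg–Marquardt
(`minpack.lm::nlsLM`, relative-RSS tolerance $10^{-8}$, at most 500
iterations); when the spectral guess already has numerically zero residual
the refinement is skipped (the gradient there is singular). Parameters are
canonicalized to $a \ge 0$, $\theta \in [0, 2\pi)$. A separate profiled
grid search (201 trial periods with the linear parameters solved exactly)
serves as an independent oracle in the test suite, never as the
implementation.

Only fits with $18 \le \tau \le 30$ (boundaries inclusive — "between 18 and
30" is read inclusively and documented here) that converged are accepted.
During-stage fits use only the **last three temperature cycles** to
minimize entrainment transients. Relative amplitude is $a$ divided by the
mean of the *unprocessed* segment, a dimensionless robustness measure.

```{r, eval = FALSE}
t20 <- temperature_protocol(20, 10, 4, 6, 72)   # 6 x (10 h 33C / 10 h 37C)
sim <- simulate_cells(20, t20, duration_h = 264, seed = 1)
traces <- preprocess_traces(sim$traces, t20)
fits <- fit_stages(traces, raw_traces = sim$traces)
period_summary(fits)
```

## Preprocessing and its edge effects

Traces are (optionally) scaled so each cell's maximum is gray level 255,
background-subtracted when background ROIs are available, and detrended by
subtracting a centered 24-h running average; the raw trace minimum is added
back so magnitudes stay comparable. Two choices here are deliberately
conservative and matter in practice:

* **Edge handling.** The running-average window is truncated (shrinks) at
  the recording edges rather than padded. The first and last half-window
  (12 h) are therefore edge-distorted and are *flagged* (`edge` column);
  stage fits exclude them. We found the distortion biases the fitted
  Before period ~0.2 h short (confirmed against the grid oracle — the bias
  is in the least-squares minimum itself, not the optimizer), which
  triples into a spurious ~0.5 circadian-hour apparent delay once the fit
  is extrapolated to an expected peak.
* **Min restoration.** "The minimum" is the per-trace raw minimum; a
  per-experiment variant would only shift all traces by a common constant.

## Peak picking and circadian time

Peak times come from a two-stage procedure: the processed trace is smoothed
with a centered 11-h running average; local maxima of the smoothed series
at least 12 h apart (half a circadian cycle — a guard against noise-induced
double peaks) are candidates; around each candidate an ordinary
least-squares parabola is fitted to the *unsmoothed* values over 30 samples
(15 h at 0.5-h sampling), and its vertex is the peak time. The parabola
must be concave-down and its vertex inside the fit window, otherwise the
candidate is rejected.

Circadian time (CT) conversions:

* **During cycles** one zeitgeber cycle is one circadian day: the time axis
  is rescaled by $24/T$ and anchored so that the *end of the cold phase is
  CT12*, independent of T.
* **Free run (Before/After)** elapsed real hours are rescaled by the
  cell's own period ($24/\tau$ circadian hours per hour). The canonical
  anchor for peripheral PER2 reporters puts the bioluminescence peak at
  CT18; stimulus-onset phases use that anchor relative to the last
  free-running peak.
* **Phase shifts** are (expected − actual peak) rescaled by $24/\tau$;
  delays (actual later) are negative, advances positive. The multiply
  convention ($\times\,\tau/24$) exists behind a documented switch but
  would make a fixed real-hour shift count for *more* circadian hours in
  longer-period cells, inverting the convention, so division is the
  default. The actual peak paired with an expected peak is the picked peak
  nearest to it within half a period; larger displacements are reported as
  ambiguous rather than silently wrapped.

## Phase-response curves

For single 10-h cold pulses, each cell contributes its onset CT (where in
its cycle the pulse hit) and its shift. Onsets in $[\mathrm{CT}6,
\mathrm{CT}18)$ form the delay group, the rest the advance group; group
means ± SEM and a Welch t-test carry the statistics, while a 4th-order
polynomial fitted on CT unwrapped to $[6, 30)$ is display-only. The
package's pulse-experiment design uses a *moderate* pulse strength
(`forcing_eps = 0.3` in the generator): the Poincaré oscillator's delay
region is steep, and stronger pulses produce delays beyond half a cycle
that no peak-based method can pair unambiguously — with the ±τ/2 pairing
rule they would alias into apparent advances. At the chosen strength the
true shifts (checked against the simulator's own phase series) are a few
circadian hours, the scale single cold stimuli produce in peripheral
oscillators.

## Circular statistics

Phases map to angles by $2\pi\,\mathrm{CT}/24$ (CT0 at angle 0,
counterclockwise). With $\bar R$ the resultant length of the unit vectors:

* **Rayleigh**: $Z = n \bar R^2$, with the series approximation
  $p = \exp\{\sqrt{1 + 4n + 4(n^2 - Zn)} - (1 + 2n)\}$. The test suite
  verifies the approximation against a Monte-Carlo uniform null and checks
  the type-I error rate at $\alpha = 0.05$.
* **Watson–Williams** (two groups): $F = K (N-2)\,(R_1 + R_2 - R) / (N -
  R_1 - R_2)$ with $K = 1 + 3/(8\hat\kappa)$, $\hat\kappa$ estimated from
  the within-group mean resultant via the standard piecewise
  approximation, referred to $F(1, N-2)$. A flag reports when the
  concentration assumption ($\bar R_w \ge 0.45$) is doubtful. The
  commercial package historically used for these tests is re-implemented
  here at the formula level, so small numeric differences against it are
  attributable to its unpublished internals.

## The synthetic generator

Real recordings for this protocol class are not publicly deposited, so the
generator is a first-class module: every analysis step is validated against
its ground truth. Each cell is a stochastic Poincaré (amplitude–phase)
oscillator, the standard minimal circadian limit-cycle model:

$$
\begin{aligned}
dx &= \left[-\tfrac{2\pi}{\tau_i} y + \lambda x (A - r) + K(\bar x - x)
      + \varepsilon z(t)\right] dt + \sigma A\, dW_x\\
dy &= \left[\;\;\tfrac{2\pi}{\tau_i} x + \lambda y (A - r) + K(\bar y - y)
      \right] dt + \sigma A\, dW_y
\end{aligned}
$$

with $r = \sqrt{x^2+y^2}$, intrinsic periods $\tau_i$ truncated-normal in
[18, 30] h, all-to-all mean-field coupling $K$, and square-wave thermal
forcing $z(t) \in \{-\tfrac12, +\tfrac12\}$ (cold/warm) during the cycles
and 0 outside them — the forcing is the cyclic deviation from the constant
culture temperature, so free-running segments are genuinely unforced.
Integration is Euler–Maruyama at $dt = 0.05$ h; the observable
$b(t) = \mathrm{baseline}_0\, 2^{-t/\text{halflife}}
(1 + (x+A)/(2A)) + \mathcal N(0, \sigma_{obs})$ is sampled every 0.5 h
(30-min exposures).

Defaults (all config-exposed) and their reasoning:

| parameter | default | why |
|---|---|---|
| `tau_mean`, `tau_sd` | 24, 1.5 h | fibroblast-like period scatter around 24 h |
| `lambda_relax` | 0.1 /h | weakly relaxing limit cycle |
| `forcing_eps` | 0.6 rad/h | a T20 cycle entrains a 24-h cell within ~3 cycles |
| `coupling_K` | 0 /h | dispersed culture; dense cultures use positive values |
| `noise_phase_sd` | 0.02 rad/√h | leaves residual During-period scatter of a few percent |
| `noise_obs_sd` | 3 gray | smooth but visibly noisy traces |
| `baseline0`, `damping_halflife_h` | 150 gray, 120 h | slow decay; a 10–11-day recording retains ~25% of its initial signal, comfortably above the 10% viability cutoff that defines an analyzable cell |
| `init_phase_kappa` | 0 | unsynchronized start; coupling experiments use ~2 (a plated culture is partially synchronized, and a strongly coupled population started from uniform phases would first *damp itself* through a near-zero mean field) |

The movie renderer places each cell as an isotropic Gaussian spot
(σ = 1.5 px, a compact clearly visible cell at 10× magnification) whose
integrated intensity equals the trace value, moving by a reflected random
walk, over constant background with Gaussian noise (σ = 1 gray) and
optional "hot pixels" for outlier-removal testing. These defaults were
chosen so the scene resembles usable recordings — cells well above the
noise floor; with substantially dimmer or broader spots, single-cell
tracking of this kind is not expected to work on real data either.

What the generator does **not** emulate: transcription–translation network
mechanisms, spatially local (non-mean-field) coupling, paracrine
signalling, stage drift, non-Gaussian camera noise, cell division, death,
or overlapping/merging cells. Passing tests therefore demonstrate that the
chain is correct and well calibrated under these statistical conditions,
not that it is robust to every pathology of real movies.

## Imaging-chain design

* **Kalman-type temporal denoising**: per pixel, the documented scalar
  recursion with measurement variance $R = g/(1-g)$ and process noise
  $Q = 1-g$, so the update weight converges to $1-g$ (an exponentially
  weighted average with `gain` $g$ the weight of the running estimate) and
  `gain = 0` is exactly the identity. The first frame passes through
  unchanged. This recursion is one documented interpretation of the
  plugin-style stack filters whose exact semantics are unpublished.
* **Impulse removal before smoothing.** The chain removes median-deviation
  outliers (radius 1, threshold 100, strict `>`, replicated edges)
  *before* temporal smoothing: smoothing first smears a hot pixel into a
  multi-frame tail that passes the spatial threshold yet dominates
  intensity normalization — we observed it hijacking the tracker entirely.
  The median filter is idempotent in its intended regime (sparse impulses
  on smooth background); on dense high-variance noise a second pass can
  still change pixels, since medians are recomputed from the modified
  frame.
* **Tracking** is a globally optimal dynamic program over per-frame local
  intensity maxima: path score = Σ normalized intensity − penalty × Σ
  squared displacement, displacement capped per frame. A fixed-position
  track (`fixed_track()`) serves immobile cells measured with manual ROIs,
  so one extraction path serves both. Tracking runs on the smoothed stack;
  quantification extracts from the *unsmoothed* impulse-cleaned stack
  (temporal smoothing's phase lag costs more fidelity at 24-h periods than
  its noise reduction buys), over a square window (3×3 default,
  config-exposed; the rendered-movie validation uses 5×5).
* **Viability QC**: excluded are cells whose final-day mean falls below
  10% of their first-day mean ("strong reduction") or with no detectable
  peak in the last 48 h ("loss of rhythmicity") — operational readings of
  the usual informal criteria, both config-exposed, with machine-readable
  reasons.

## Numerical choices and degenerate inputs

* Inclusive boundaries everywhere a band is stated (18/30 h circadian
  filter, ±1 h entrainment tolerance).
* Constant segments yield $a = 0$ fits with a warning, not an error;
  non-convergence is a flag; an empty peak set is an empty table.
* The zero-shift control (validating the expected-peak machinery) runs
  with phase diffusion off: a diffusing phase *genuinely* shifts — the
  pipeline measuring it as nonzero is correct, so it cannot serve as a
  null control for the measurement chain itself.
* Entrainment-monotonicity is asserted on a forcing sweep up to full
  locking; beyond it, square-wave waveform distortion adds a small
  re-increase in the fitted-period deviation, which is a property of the
  fit, not of entrainment.
* Problem sizes in tests and the acceptance script: 20-cell demo
  populations, 60-cell pulse experiments, 3-cell 96×96 movies, 10⁴-replicate
  Monte-Carlo calibrations — sizes at which all checks complete in a few
  minutes on one core while keeping Monte-Carlo error well below the
  asserted margins.

## Known limitations

* Plain (undamped) cosine fitting: the decaying envelope is handled by
  detrending, not modelled; strongly damped cells bias the amplitude, and
  the amplitude-response fold partly cancels this by construction.
* Peak-based phase shifts cannot resolve displacements beyond half a
  period; near-half-cycle responses are reported as ambiguous.
* The Watson–Williams test presumes comparable, reasonably high
  concentration; the implementation warns rather than refuses below the
  standard validity threshold.
* No automatic cell detection: tracks are seeded (or fixed ROIs supplied)
  by the user, as in the manual workflow the package formalizes.
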