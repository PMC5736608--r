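---
title: "Theta-gamma coupling: models, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Theta-gamma coupling: models, estimators, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(thetagamma)
```

## The scientific problem

Hippocampal–prefrontal communication during spatial working memory is
thought to ride on cross-frequency coupling: the phase of the hippocampal
theta oscillation (4–12 Hz) modulates the amplitude of prefrontal gamma
oscillations, with slow gamma (30–70 Hz) and fast gamma (80–120 Hz)
preferring different theta phases. This package quantifies that coupling
from local field potentials (LFPs) and relates it to spiking and behavior.
Because the underlying animal recordings are not publicly deposited, the
package ships a synthetic generator whose ground truth is known exactly;
all validation rests on recovering planted parameters.

## The coupling estimator

The estimator chain is:

1. **Theta phase.** The phase-providing trace is bandpassed with a
   linear-phase windowed-sinc (Hamming) FIR kernel applied forward and
   backward (exactly zero group delay), and the instantaneous phase is the
   argument of the analytic signal (FFT Hilbert construction). The
   convention is cosine-like: phase 0 at oscillation peaks, ±π at troughs.
2. **Gamma power.** The amplitude-providing trace is convolved with
   two-cycle complex Morlet wavelets (Gaussian envelope
   σ_t = n_cycles/(2πf), kernel truncated at ±5σ_t, L1-normalized) and the
   squared magnitude averaged across the in-band frequency rows.
3. **Weighted MRL.** Phases are binned into 100 bins of width π/50 with
   centers −π + (k − ½)π/50; the bin-mean powers w_k weight unit phasors at
   the bin centers. MRL = |Σ w_k e^{ic_k}| / Σ w_k; the resultant's
   argument is the preferred phase.

Weights are raw bin means (no z-scoring or normalization beyond the
denominator); nothing in the estimator presumes a modulation shape.

A raised-cosine **power** profile P(φ) ∝ 1 + m·cos(φ − φ₀) has the exact
closed form MRL = m/2, direction φ₀. The generator therefore applies the
raised cosine in the power domain — the gamma carrier's amplitude envelope
is base·√(1 + m·cos(θ − φ₀)) — so that the power-weighted MRL the
estimator computes has an analytic target. (Applying the raised cosine to
the amplitude instead would square inside the weights and give
MRL = m/(1 + m²/2), which has no clean small-m reading; depth then stops
being interpretable as twice-the-MRL.)

### Why the wavelet-path MRL is "small"

A two-cycle Morlet at frequency f has spectral width σ_f = f/2: at 40 Hz
the kernel still responds appreciably at 8 Hz. Any theta-band or 1/f power
therefore leaks into the 30–150 Hz rows as phase-independent background,
diluting the weighted MRL multiplicatively (observed ≈ 0.46·m/2 on
noiseless synthetic pairs with the default amplitude ratios). This is a
property of the prescribed front end, not a bug — it is why coupling
values measured this way on real recordings are numbers like 0.02–0.03 —
and it is left uncorrected. The alternative estimator
(`amp_method = "hilbert"`: sharp FIR bandpass + squared Hilbert envelope)
isolates the band to better than −80 dB and attains the closed form; the
exact-recovery tests use it, while the wavelet default is validated by
monotonicity in m, direction recovery, and time-shift surrogates.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| theta band | 4–12 | Hz | field-standard rodent theta |
| slow / fast gamma | 30–70 / 80–120 | Hz | band definitions under study |
| wavelet cycles | 2 | — | fixed short-window convention |
| phase bins | 100 (π/50) | rad | profile resolution |
| comodulogram phase bands | centers 4–20, width 0.5 | Hz | step = bandwidth, contiguous |
| min. PAC data | 10 | s | ≈ 80 theta cycles; below this the MRL estimate is dominated by sampling noise |
| min. per-epoch data | 0.5 | s | center-arm runs are short; shorter epochs dropped and counted |
| gamma-peak separation | 0.1 | s | ≤ 1 peak per theta cycle |
| CCG coincidence window | ±1 (inclusive) | ms | "within 1 ms" read inclusively |
| CCG curve bins | 0.5 over ±50 | ms | centered on multiples of 0.5 ms |
| unit inclusion | L-ratio ≤ 0.1, isolation ≥ 10 | — | inclusive bounds; missing metric ⇒ excluded with reason |
| quartile epoch length | 2 | s | the split's epoch duration is not dictated by theory; 2 s balances per-epoch MRL noise against epoch count, and is configurable |

## Filter design

The FIR order is chosen as max(3 cycles of the band's low edge,
3.3·rate/Δf) taps with Δf = min(low, high − low)/2, the Hamming-window
transition rule. The second term is the binding one for narrow bands: a
0.5-Hz comodulogram band at 2 kHz needs ~26,000 taps or its transition
band would be wider than its passband; the first term alone (a 4-Hz-wide
transition) could not realize such bands, nor meet 40 dB of stopband one
octave below a 4-Hz low edge. Filtering is FFT convolution with the
centered symmetric kernel, applied twice (forward–backward), so cost is
independent of kernel length. One kernel length minus one sample at each
edge is flagged as transient-contaminated; all coupling functions drop
flagged samples, and short traces (< 3 kernel lengths) are errors rather
than silently unreliable estimates.

## The synthetic generator

What it emulates: a vHPC trace (theta cosine + 1/f noise, synthesized by
spectral shaping of white Gaussian noise, exponent 1.0), an mPFC trace
(phase-lagged theta + two gamma carriers + 1/f noise), gamma carriers at
band-center frequency with ±10% frequency jitter redrawn each theta cycle
(pure tones would make comodulogram peaks unrealistically narrow),
power-domain raised-cosine modulation at configurable depth and preferred
phase, von Mises spike–gamma locking via thinned inhomogeneous Poisson
processes with intensity r₀·exp(κ·cos(φ − ψ))/I₀(κ) (mean rate exactly
r₀), and a trial structure of paired sample/choice center-arm epochs in
which the choice-epoch slow-gamma depth is raised by `phase_effect` on
correct trials only. Correctness is Bernoulli(0.8), matching
post-criterion performance on a delayed non-match-to-place task.

Defaults (8-Hz theta of unit amplitude, gamma amplitudes 0.3/0.2, noise SD
0.2, 20 trials × 2-s epochs, 2 kHz sampling, 5-Hz units at κ = 2) are
chosen once as representative of rodent recordings; the recordings'
actual noise spectrum and SNR are unpublished, so these are conventional
values, not fits.

What it does **not** emulate: waveform asymmetry of real theta, volume
conduction, non-stationary running-speed effects, bursting spike
statistics, electrode drift, or line noise. Passing tests therefore show
the estimators are correct and calibrated, not that real recordings meet
their assumptions.

## Numerical and design choices

- **Pooling.** One PAC estimate pools all selected samples (epochs
  concatenated before binning) rather than averaging per-trial estimates;
  per-epoch values are computed separately where paired tests need them.
- **Surrogates.** Significance floors use circular time shifts of the
  power series (uniform ≥ 1 s, 200 draws), which preserve both marginals
  and autocorrelations while destroying the phase–power alignment.
- **Gamma peaks** are detected on the filtered voltage (not its envelope),
  retained greedily highest-first with a symmetric 100-ms exclusion zone;
  amplitude ties break toward the earlier peak. No amplitude threshold is
  applied beyond the separation rule (an optional envelope threshold flag
  exists, default off).
- **CCG.** Every spike may participate in multiple pairs (raw pair
  count), no jitter correction. Curve bins are centered on multiples of
  0.5 ms with round-half-to-even assignment, which makes the (a,b) curve
  the exact mirror of (b,a) including boundary lags. Same-stereotrode
  pairs are excluded in the pipeline (shadowing artifacts).
- **n:m grid** defaults to n ∈ 1..4, m ∈ 1..16 with entry (n, m) the
  resultant of n·φ_θ − m·φ_γ computed per sample, no binning.
- **ANOVA** uses Type II sums of squares (identical to Type I/III on
  balanced designs, robust to mildly unbalanced trial counts). No
  multiple-testing correction is applied; all tests are reported so users
  may adjust.
- **Nested data.** Correlations with several sessions per animal get an
  animal-indicator OLS regression as the significance test; no random
  effects (the hierarchical structure is shallow and the indicator model
  keeps degrees of freedom explicit).
- **Degenerate inputs** error loudly: constant traces (undefined phase),
  all-zero weights, empty trains (rate 0), < 4 distinct coupling values
  (quartiles undefined), all-incorrect sessions under a correct-only
  selector.
- **Epoch convention.** All epochs are half-open [t_start, t_end) seconds
  from session start.

## Problem sizes

Exact-recovery checks use 60-s noiseless pairs (closed-form PAC,
comodulogram localization); property checks use 20–45-s pairs. Calibration
simulations use 2,000–2,500 replicates for type-I error, 100 replicates
for the Poisson CCG expectation, and 500 replicates for null-slope CI
coverage. The end-to-end experiment uses 10 sessions of 20 trials × 2-s
epochs per condition, the scale at which the paired contrast has high
power for a planted depth difference of 0.2 while a null difference stays
at chance.

## Known limitations

- The two-cycle wavelet's bandwidth makes the default MRL scale
  signal-composition-dependent (see above); compare MRLs only within a
  fixed front-end configuration.
- Weighted-MRL profiles with grossly non-uniform phase coverage (e.g.
  nearly silent phase bands in noiseless constructions) can inflate; the
  estimator assumes the phase series sweeps the circle, which holds for
  any oscillatory or noisy band.
- The Watson–Williams approximation degrades below κ ≈ 1; the function
  warns rather than refusing.
- Rayleigh p-values use the standard series approximation, accurate for
  n ≥ 10 (the enforced minimum).
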