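---
title: "Multiscale functional connectivity by multivariate variational mode decomposition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale functional connectivity by multivariate variational mode decomposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modefc)
```

## The problem and the model

Parcellated fMRI time series mix processes with very different timescales:
near-DC drifts from scanner instability, residual motion and slow
physiology; BOLD fluctuations of neural origin in the 10–200 mHz band;
respiration around its ~250 mHz fundamental; and vascular/cardiac
pulsations in the 350–800 mHz range, parts of which fold back into lower
frequencies by aliasing at typical repetition times. A single correlation
matrix computed on the raw series conflates the connectivity signatures of
all of them.

`modefc` decomposes the whole multichannel record at once into `K`
*multivariate intrinsic modes*: amplitude- and frequency-modulated
narrow-band components that share one central frequency `ω_k` across all
channels. The modes jointly minimize the summed bandwidth of their analytic
(one-sided) spectra subject to reconstructing the input — the multivariate
extension of variational mode decomposition. The solver is ADMM in the
frequency domain:

1. **Mode update** (per mode `k`, channel `c`): a Wiener-like filter
   `û_{k,c} ← (x̂_c − Σ_{j≠k} û_{j,c} + λ̂_c/2) / (1 + 2α(ω − ω_k)²)`
   applied on the nonnegative half-spectrum.
2. **Frequency update**: `ω_k` moves to the power-weighted spectral
   centroid pooled over *all* channels, which is what ties the channels to
   a common frequency.
3. **Dual ascent** (optional): `λ̂ ← λ̂ + τ(x̂ − Σ_k û_k)` pushes the mode
   sum toward exact reconstruction.

Iterations stop when the summed relative change of the mode spectra falls
below `tol`. Modes are returned sorted by ascending central frequency; the
residual is defined as input minus mode sum, so modes + residual always
reproduce the input exactly. The iteration loop is compiled
(RcppArmadillo); everything else is plain R.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `k` | 10 | — | number of modes; 10 spans drift to cardiac harmonics at TR = 0.72 s |
| `alpha` | 1000 | — | bandwidth penalty; larger → narrower modes |
| `tau` | 0 | — | dual-ascent step; 0 tolerates broadband noise, 2.5 enforces exact reconstruction on clean signals |
| `tol` | 1e-7 | relative | convergence threshold on spectral change |
| `max_iter` | 500 | — | iteration cap |
| `init` | `"peaks"` | — | center-frequency initialization (below) |
| `boundary` | `"mirror"` | — | mirror-extend by T/2 per side to damp edge ringing |

`tau` deserves a comment: with `tau = 0` the Wiener filters act as a
denoiser — on noisy data the un-modeled broadband noise stays in the
residual, which is usually what one wants for fMRI. On noiseless or
near-noiseless signals, a positive `tau` (we use 2.5 in validation of the
reconstruction contract) drives the relative reconstruction error below
1e-2, at no cost to frequency recovery. Relatedly, on noisy records the
`tol = 1e-7` threshold is often not reached within 500 iterations because
one surplus mode keeps slowly drifting across the noise floor; the
`converged` flag then reports `FALSE` while the modes that carry signal are
stable after a few dozen iterations.

### Initialization

ADMM converges to a local optimum of a non-convex problem, so where the
center frequencies start matters. The package's default, `init = "peaks"`,
places the `K` initial frequencies on the `K` strongest local maxima of
the channel-summed power spectrum, skipping candidates closer than half
the Wiener filter's half-width `1/sqrt(2α)` to an already chosen one and
filling any shortfall uniformly. The rationale is the strongly
low-frequency-weighted spectrum of BOLD data: a uniform grid over the
lower half-band leaves no initial center between DC and the first grid
point, so at moderate `K` the drift and the slowest neural rhythm end up
competing for a single mode and merge. We observed exactly this failure on
synthetic cohorts (drift and a 25 mHz component merging at `K = 6`), and
spectrum-peak initialization removes it. Uniform, uniform-in-log, random
(seeded) and all-zero initializations remain available; the cross-check
against the univariate solver uses `uniform` on both sides so the
comparison is initialization-identical.

### Numerical conventions

* Half-open physiological bands, lower bound inclusive: trend [0, 10) mHz,
  neurophysiological [10, 200), respiratory [200, 350), vascular/cardiac
  [350, 800), `other_high` above. Bands are truncated at Nyquist (694 mHz
  at TR = 0.72 s, so `other_high` is empty there) and always tile
  [0, Nyquist], making band classification a total function.
* Bandwidth is reported as `2·sqrt` of the power-weighted second central
  moment of the channel-summed spectrum (an RMS bandwidth; the factor 2
  makes a symmetric two-point spectrum with separation `d` report `d`).
  Other conventions differ by fixed factors.
* Fisher-Z clips `|r| = 1` to `1 − 1e-7` before `atanh`.
* Two modes whose final frequencies collide within one frequency bin are
  both kept, with a warning — modes are never merged.
* A constant channel contributes only to the near-DC mode; an all-constant
  input warns and returns degenerate near-DC modes rather than failing.
* The instantaneous frequency of an identically zero channel is reported
  as 0 by convention.

## The permutation null and edge tests

Per participant and mode, connectivity is the Pearson correlation matrix
of the mode waveforms, Fisher-Z transformed. The null hypothesis of no
cross-ROI dependence is simulated by *independently* permuting the time
samples of each channel and recomputing the matrix: independent shuffles
destroy cross-channel alignment while preserving each channel's amplitude
distribution. (A permutation shared across channels would preserve the
correlations and produce a degenerate null.)

Group-level edge significance contrasts the `N` observed Fisher-Z values
per edge with the pooled null values via a Welch t statistic; its p-value
is the fraction of label-shuffled statistics at least as extreme (two
sided), with the tail continuity correction `p = (b+1)/(n+1)`. Label
permutations are shared across edges within one call, the standard
practice in neuroimaging permutation testing. Benjamini–Hochberg step-up
at `q = 0.001` over the upper-triangle edges gives the significance mask.

A structural property worth knowing: a permutation p-value cannot go below
`1/(n_stat_perm + 1)`, so BH at level `q` over `E` edges can only flag
edges at all when `E ≤ q·(n_stat_perm + 1)`. With the default
`n_stat_perm = 10000` and `q = 0.001` this caps `E` at 10 edges for a
single isolated effect; power validation therefore uses a 4-ROI network
(6 edges). For large parcellations the test is correspondingly
conservative — many jointly significant edges raise the BH threshold, but
a lone weak edge in a 90-ROI matrix cannot reach significance at this
resolution.

## What the synthetic cohorts emulate

`default_cohort_spec()` is the package's evaluation cohort: 10
participants, 20 ROIs in 4 modules, 1200 samples at TR = 0.72 s, with

* a participant-specific drift (integrated white noise low-passed below
  8 mHz, random loadings per participant),
* three neural oscillations at 25, 60 and 110 mHz with *shared*
  module-structured loadings (the reproducible connectivity templates),
  each loaded on an overlapping pair of modules with alternating module
  signs and per-ROI magnitudes in [0.8, 1.2],
* a respiratory tone at 250 mHz with participant-specific random loadings,
* per-participant jitter of ±10% on center frequencies and ±20% on
  amplitudes, slow (5 mHz) amplitude modulation of depth 0.2 on the tones,
* white noise with `noise_sd = 1.25`, which puts the signal-to-noise ratio
  near 0 dB given the component variances above.

Ground truth (loadings, realized frequencies, component waveforms, planted
connectivity patterns) is returned alongside the signals, so decomposition
accuracy, band selection, FC recovery and the reproducibility contrast can
all be scored objectively. Component frequencies above Nyquist are refused
unless aliasing is explicitly requested, in which case they are folded to
their alias with a warning — mimicking aliased cardiac content.

What these cohorts do *not* emulate: 1/f-shaped background spectra,
spatially correlated noise, hemodynamic variability across regions, head
motion spikes, and the slow non-stationarity of real scanning sessions.
Passing the package's validation therefore demonstrates the correctness of
the algorithms under the stated generative model, not performance claims
on any particular real dataset.

One artifact of the evaluation design is worth naming: with `K = 6` modes
and five planted components, the surplus mode settles on the strongest
concentration of residual noise. Its central frequency is roughly uniform
over the spectrum, so in about a quarter of decompositions it falls inside
the 10–200 mHz band and is — correctly, by its frequency — selected as
neurophysiological. Cohort-level selection by majority vote across
participants is robust to this; per-participant selection necessarily is
not, and validation scores selection at cohort level while grouping modes
for the reproducibility contrast by matching them to the planted
components.

## Problem sizes used in validation

The test suite and the acceptance script run, per invocation: 20 seeded
cohorts (10 participants × 20 ROIs × 1200 samples, `K = 6`) for band
selection, of which the first 10 are reused for the reproducibility
contrast and the first for FC recovery; 50 signal-free replicates
(20 participants × 10 ROIs, 200 null permutations, 2000 label
permutations) for null calibration; 20 replicates of the single-edge
power scenario (4 ROIs, 10000 label permutations); and 5 univariate
two-tone fixtures for the oracle equivalence check. These sizes were
chosen so the whole validation runs on a laptop-class single core in
minutes while keeping all binomial success criteria meaningful.

## Known limitations

* `K` and `α` are user choices; the package deliberately does not select
  them automatically.
* Static connectivity only; the decomposition is per participant, with no
  group-joint variant.
* Mode identity across participants is by index after the
  ascending-frequency sort; when a surplus mode wanders between bands in
  a subset of participants, index matching blurs (see above).
* Empirical-mode (sifting) and chirp-mode decompositions are out of scope;
  the solver implements the variational formulation only.
* The permutation edge test inherits the p-value resolution limit above;
  for dense parcellations at strict `q`, consider more label permutations.
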