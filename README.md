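# modefc

Multiscale functional connectivity from multivariate variational mode
decomposition (MVMD) of fMRI ROI time series.

Resting-state and task fMRI signals are a superposition of processes living
at different timescales: slow scanner/physiological drifts (≪ 10 mHz),
neurophysiologically driven BOLD fluctuations (10–200 mHz), respiration
(~250 mHz fundamental) and cardiac/vascular pulsations (~350–800 mHz,
partly aliased at typical repetition times). Conventional functional
connectivity (FC) mixes all of these into one correlation matrix. `modefc`
separates them first: it jointly decomposes all ROIs into `K` narrow-band
**multivariate intrinsic modes** that share central frequencies across
ROIs, labels each mode by its physiological band, and then estimates an FC
matrix *per mode*, with permutation-based significance and
cross-participant reproducibility statistics.

It is aimed at researchers who already have parcellated ROI × time matrices
(one delimited text file per participant) and want frequency-resolved
connectivity without hand-tuned band-pass filtering.

## The model

A `C`-channel signal `x(t)` is modeled as a sum of `K` band-limited
multivariate oscillations plus residual,

```
x_c(t) = Σ_k u_c^(k)(t),   k = 1..K,
```

where each mode `u^(k)` concentrates around a central frequency `ω_k`
common to all channels. The modes solve the variational problem

```
min_{u,ω}  Σ_k Σ_c ‖ ∂_t [ ( δ(t) + j/(πt) ) * u_c^(k)(t) ] e^{-jω_k t} ‖²
s.t.       Σ_k u_c^(k)(t) = x_c(t),
```

i.e. minimal summed analytic bandwidth subject to reconstruction. ADMM in
the frequency domain alternates a Wiener-like update
`û_{k,c} ← (x̂_c − Σ_{j≠k} û_{j,c} + λ̂_c/2) / (1 + 2α(ω − ω_k)²)`, a
center-frequency update by the channel-pooled spectral centroid, and an
optional dual ascent on the reconstruction constraint. The bandwidth
penalty `α` (default 1000) and mode count `K` (default 10 at TR = 0.72 s)
are the two parameters that matter.

Downstream, per-mode FC is Pearson correlation between ROI mode waveforms,
Fisher-Z transformed, averaged across participants, and tested against a
null built by independently permuting each channel's time samples
("shuffled-mode" null); edge-level permutation t-tests are corrected by
Benjamini–Hochberg FDR at `q = 0.001`. Reproducibility is the Pearson
correlation of vectorized FC matrices over all participant pairs.

## Worked example

```r
library(modefc)

# a synthetic 10-participant cohort with known band structure:
# drift + neural oscillations at 25/60/110 mHz + respiration at 250 mHz
cohort <- generate_cohort(default_cohort_spec(seed = 1))
fit <- mvmd(cohort$signals[[1]], k = 6)
fit
#> <mvmd_decomp> 6 modes, 20 channels x 1200 samples
#> central frequencies (mHz):   1.4,  24.3,  60.5, 107.1, 227.9, 535.4
#> NOT converged in 500 iterations; relative reconstruction error 0.394

tidy(fit)
#> # A tibble: 6 x 5
#>    mode central_freq_hz bandwidth_hz rel_energy band
#>   <int>           <dbl>        <dbl>      <dbl> <chr>
#> 1     1         0.00136       0.0218     0.139  trend
#> 2     2         0.0243        0.0177     0.154  neurophysiological
#> 3     3         0.0605        0.0195     0.100  neurophysiological
#> 4     4         0.107         0.0148     0.181  neurophysiological
#> 5     5         0.228         0.0260     0.110  respiratory
#> 6     6         0.535         0.0556     0.0269 vascular_cardiac

select_neurophysiological(fit)
#> [1] 2 3 4
```

The decomposition puts the drift near DC, one mode on each planted
oscillation (24/61/107 mHz ≈ 25/60/110 with per-participant jitter), and
respiration at 228 mHz outside the neural band; the three neural modes
carry ~44% of the signal energy. (At this signal-to-noise ratio — about 0 dB — the
Wiener filters deliberately leave broadband noise in the residual, hence
the large "reconstruction error" and the unconverged-at-500-iterations
flag; the mode estimates themselves are stable long before that.)

Connectivity and reproducibility for one neural mode:

```r
ms  <- lapply(cohort$signals, mvmd, k = 6)
res <- fc_analysis(ms, mode_index = 2, n_perm = 200, seed = 1)
res
#> <fc_result> mode 2: 20 x 20 group connectivity over 10 participant(s)
#> 45 of 190 edges significant at FDR q = 0.001
glance(pairwise_similarity(res))
#> # A tibble: 1 x 6
#>    mode n_pairs median    q1    q3  mean
#>   <dbl>   <int>  <dbl> <dbl> <dbl> <dbl>
#> 1     2      45  0.976 0.964 0.980 0.823
```

The 45 significant edges are exactly the 45 ROI pairs whose modules carry
the planted 25 mHz component, and the FC pattern is near-identical across
participants (median pairwise similarity 0.98). `autoplot(res)` draws the matrix with
the group mean in the lower triangle and only significant edges in the
upper triangle.

For file-based cohorts use `read_timeseries()` / `read_modules()` and
`run_pipeline(pipeline_config(...))`, or the CLI:

```sh
Rscript inst/cli/modefc.R run --config analysis.yaml --seed 1 --out run/
```

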