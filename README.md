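# twinsync

Pairwise physiological synchrony in twin cohorts: beat-to-beat-interval
(BBI) heart-rate dynamics and EEG band-power coupling across repeated
meditation sessions.

## The problem

When two people — especially co-twins — meditate together repeatedly, do
their physiological signals co-fluctuate more than those of unrelated
pairs? `twinsync` implements the full analysis chain for a twin-cohort
design (monozygotic pairs, a dizygotic pair, age-matched controls) and, in
the absence of deposited raw recordings, a synthetic dyadic-cohort
generator with known ground-truth coupling so every stage can be validated
by parameter recovery. It is written for researchers analyzing dyadic
wearable or EEG data and for anyone auditing the statistics of this study
design.

## Methods at the core

**Heart rate.** Raw tachograms `RR(t_i)` are cleaned by a time-varying
quantile-threshold cascade (missed beats split, extra beats merged, ectopic
beats recentred, isolated outliers interpolated; rejection scale
`c = 5.2`), resampled to 1 Hz with the shape-preserving cubic Hermite
(PCHIP) interpolant, and smoothed with a 10-s moving average. For an
aligned dyad the package computes

* mean sliding-window Pearson correlation: windows of 300 s, hop 60 s,
  `r̄ = mean(r_w)` over full windows;
* mean absolute difference `mean |a(t) − b(t)|` (ms).

Dyads are organized into pairing schemes `T` (MZ co-twins), `DT` (DZ),
`CT` (twin–control) and `N` (cross-pair twins); groups are compared with
Wilcoxon rank-sum tests and a mixed-effects model
`absdiff ~ group * time + (1 | pairing)`.

**EEG.** Paired recordings are high-passed (0.5 Hz), notched (60 Hz),
length-equalized, cut into 1.5-s epochs every 0.1 s, jointly screened by a
pooled probabilistic epoch rejection, decomposed with complex Morlet
wavelets (1.5–50 Hz, 3→30 cycles), averaged into six bands
(δ 1.5–4, θ 4–7, α 7–12, σ 12–18, β 18–30, γ 30–50 Hz), smoothed over
2 min and reduced to ~20 coarse time points per channel × band. Dyad
correlation maps are masked by a sham-pair bootstrap: 1000 draws of m
non-co-twin pair maps, nearest-rank 5th/95th percentile limits, twin-mean
values inside the limits set to zero.

## Worked example

```r
library(twinsync)

# a coupled dyad: latent correlation 0.6, 2 artifacts/min injected
g <- generate_coupled_bbi(bbi_params_from_rho(0.6, total_sd = 50,
                                              artifact_rate = 2),
                          duration = 900, seed = 42)
g$a
#> <bbi_tachogram> a / s1: 915 intervals over 900.4 s, mean 984.0 ms, 53 flagged

pp_a <- preprocess_bbi(g$a)   # correct -> 1 Hz PCHIP -> 10-s smoothing
pp_b <- preprocess_bbi(g$b)
head(pp_a$report, 3)
#>   index      time    old_ms   new_ms   rule
#> 1    78  76.75969 1965.3364 982.6682 missed
#> 2   105 105.90367 1891.8243 945.9121 missed
#> 3   115 116.40206  347.0005 991.4300  extra

windowed_pearson(pp_a$series, pp_b$series)$mean_r
#> [1] 0.5615  # 10 windows; recovers the injected coupling of 0.6
mean_abs_diff(pp_a$series, pp_b$series)$mad_ms
#> [1] 28.1    # ms

generate_roster()
#> <twin_roster> 21 participants (3 MZ pairs, 1 DZ, 13 controls), 17 sessions, 357 slots
```

The tachogram report shows the corrector splitting merged (missed-beat)
intervals near 1970 ms back to ~985 ms and merging spurious extra beats;
the windowed correlation of 0.56 recovers the generator's latent coupling
of 0.6, and the mean absolute difference of 28 ms reflects equal baselines
with individual fluctuation.

For a full run (simulation → preprocessing → synchrony tables → EEG maps →
sham masking → demographics):

```r
run_pipeline(default_run_config(seed = 1, out_dir = "out"))
```

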