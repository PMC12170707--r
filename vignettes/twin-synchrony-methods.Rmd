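---
title: "Methods: pairwise physiological synchrony in twin cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pairwise physiological synchrony in twin cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinsync)
```

## The analysis problem

`twinsync` quantifies how similar two people's physiology is while they share
an activity — here, repeated group meditation sessions in a cohort of
monozygotic (MZ) and dizygotic (DZ) twin pairs plus age-matched controls.
Two data streams are analyzed:

1. **Heart-rate dynamics.** Each participant wears a wrist sensor producing a
   *tachogram*: the irregular sequence of beat-to-beat intervals (BBI, ms)
   against beat time. Pairwise similarity of two participants' interval
   dynamics is scored per session.
2. **EEG band power.** Paired 32-channel recordings are reduced to slow
   per-channel, per-band power time courses, correlated within dyads, and
   screened against a sham-pair (non-co-twin) bootstrap null.

Four pairing schemes structure the heart-rate comparison: `T` (MZ co-twins),
`DT` (DZ co-twins), `CT` (a twin with an age-matched control) and `N` (twins
from different pairs). The scientific question is whether co-twins are more
synchronized than unrelated meditators.

## BBI preprocessing

A raw wearable tachogram contains ectopic, missed and extra beats. The
corrector (`detect_correct_outliers()`) is a time-varying-threshold decision
cascade: successive interval differences (dRR) and deviations from a rolling
median are normalized by a rolling quantile-deviation estimate (half the
local interquartile range over a 91-interval window), and intervals beyond
`c_scale = 5.2` of that scale are classified:

* interval near twice the local median → *missed beat*, split in half;
* two adjacent intervals summing to one local median → *extra beat*, merged;
* short–long alternation → *ectopic/displaced beat*, repaired by removing or
  recentring the offending beat depending on whether the pair sums to one or
  two local medians;
* remaining isolated outliers → replaced by interpolation from unflagged
  neighbours.

Thresholds are floored at 20 ms — below wearable beat-timing resolution no
deviation is treated as evidence of an artifact — which keeps the corrector
an exact identity on clean recordings. The cascade is iterated to a fixpoint
(corrections slightly shift local statistics), making the operation
idempotent. If more than 20 % of intervals are corrected a warning is
raised; the data are kept, flagged, and the pairing can be excluded at the
scheme level.

Corrected tachograms are resampled to exactly 1 Hz with a shape-preserving
piecewise cubic Hermite interpolant (`interpolate_1hz()`), with knots at the
time of the beat *ending* each interval — the attribution convention matters
only by one interval but is fixed here so pairs align identically. The
integer-second grid is anchored at session start, so two participants'
series align by wall clock. A 10-s centred moving average
(`smooth_moving()`) follows; edge windows shrink symmetrically so the series
length is preserved, which keeps pair overlap bookkeeping trivial.

One consequence worth noting: the 1 Hz series estimates the *time-average*
of the interval function, i.e. the duration-weighted interval mean; with
fluctuations of SD $\sigma$ around mean $\mu$ the two means differ by about
$\sigma^2/\mu$ (≈ 2 ms at the generator defaults). Tests therefore compare
the pipeline mean to the duration-weighted mean.

## Synchrony statistics

`windowed_pearson()` slides a 300-s window in 60-s hops across the aligned
overlap, requires full windows, computes a Pearson r per window, skips
zero-variance windows, and averages the retained raw r values (no Fisher z —
the summary mirrors plain averaging of coefficients). Window placement is
anchored at the overlap start and a final partial window is discarded.
`mean_abs_diff()` averages `|a(t) − b(t)|` over the overlap; it is the
baseline-sensitive complement to the correlation (a DZ pair with baselines
1250 vs 750 ms has a large absolute difference regardless of coupling).

Groups are compared with two-sided Wilcoxon rank-sum tests (normal
approximation, mid-rank ties with variance tie correction, continuity
correction); the 0.05 threshold is annotated, never used to filter.
`fit_group_time_model()` fits `absdiff ~ group * time + (1 | pairing)` by
REML with the control (CT) group as reference; session index enters as a
numeric covariate by default (a categorical option exists). Singular fits
fall back to a plain interaction regression with a warning.

## EEG band-power pipeline

Recordings are mean-centred, high-passed at 0.5 Hz and notch-filtered at
60 Hz (zero-phase Butterworth); dyad members are truncated to equal length
from the end; 1.5-s epochs slide every 0.1 s. Epoch rejection is *pooled*:
each subject's per-epoch joint log-improbability score (sum over channels of
the mean negative log kernel-density of the channel's amplitude
distribution) is z-scored, epochs beyond z = 3 in either subject are removed
from both, so the retained time points stay aligned.

Power is computed with complex Morlet wavelets on a 1-Hz grid from 1.5 to
49.5 Hz, with cycles rising linearly from 3 at 1.5 Hz to 30 at 50 Hz, and
averaged in six bands (delta 1.5–4, theta 4–7, alpha 7–12, sigma 12–18,
beta 18–30, gamma 30–50 Hz; bands half-open, top band closed). Epochs are
zero-padded to the wavelet support; at the lowest frequencies a 1.5-s epoch
holds fewer than three cycles, so delta estimates lean on the padding taper
— a structural property of this parameterization, flagged rather than
hidden. Implementation note: the per-epoch zero-padded convolution power is
evaluated through the wavelet Gram matrix, `x' Re(W*W) x / L`, which is
algebraically identical to direct convolution (tested to 1e-9) but runs as
one matrix product per channel and frequency.

Band power is smoothed over a 120-s moving window of epoch start times and
exactly 20 evenly spaced points are extracted (configurable `n_points`);
correlation is computed on linear power by default with a log-power option.
Dyad maps (`pair_correlation()`) hold a Pearson r per channel × band.

## Sham bootstrap and masking

All non-co-twin pairings among the twin subjects form the sham ensemble
(`enumerate_sham_pairs()`; 2k(k−1) pairs for k twin pairs — 12 for 3 pairs).
`bootstrap_mask()` draws m sham maps per replicate — *with replacement* by
default, reading "random selections" with bootstrap semantics; a
without-replacement mode is provided since either reading is defensible —
averages them cellwise, repeats 1000 times, and takes nearest-rank 5th/95th
percentiles of the sorted means as masking limits. Twin-mean cells strictly
inside the limits are set to zero; pre-mask values are kept bit-exactly in a
sidecar field, and the per-tail probability is monotone: shrinking `alpha`
widens the limits and can only mask more.

A caveat the package makes explicit: with only 12 sham pairs and draws of
m = 3, the bootstrap limits are themselves noisy (the ensemble mean wanders
by σ/√12), so under an exchangeable null roughly 19 % of cells survive the
nominal 2 × 5 % mask rather than 10 %. The calibration test therefore uses a
large sham ensemble (150 maps), where the pass rate converges to 0.10; at
an ensemble of a dozen sham pairs the mask should be read as a display
threshold, not an exact false-positive rate. No multiplicity correction
across channels and bands is applied, matching the original analysis
convention.

## The synthetic cohort generator

No raw physiological recordings are publicly available for this cohort
design, so every stage is validated against a generator with known ground
truth
(`generate_roster()`, `generate_coupled_bbi()`, `generate_coupled_eeg()`).

* **Design.** Defaults reproduce the analyzed cohort: 3 MZ pairs + 1 DZ pair
  + 13 controls (one control serving two pairs), 17 sessions — 357
  recording slots; each pair's second member sits apart in three of sessions
  3, 4, 9, 10, 14, 15, which excludes those pairing-sessions from
  comparison while keeping the recording slot. Twin ages default to the
  recruited pairs (25, 63, 56, 76, 36, 54 years); control ages are drawn to
  match the per-pair control-group means and SDs.
* **Coupled BBI.** `BBI_i(t) = baseline_i + A_s S(t) + A_u I_i(t)` with S
  and I independent band-limited Gaussian processes (white noise smoothed by
  moving averages, band 0.01–0.1 Hz — the low-frequency heart-rate
  variability band). Beats are placed by cumulative-interval integration;
  the latent correlation between two subjects is
  $\rho = A_s^2/(A_s^2+A_u^2)$ (`bbi_params_from_rho()`). Default total
  fluctuation SD is 47 ms on a 1000 ms baseline — mid-range for relaxed
  adults. Artifacts (ectopic 40 / missed 30 / extra 30 %) are injected
  post-hoc at a configurable events-per-minute rate with positions logged.
* **Coupled EEG.** Per channel: 1/f background plus six band carriers
  (2.5–40 Hz) amplitude-modulated by slow (< 0.05 Hz) envelopes; a dyad's
  band envelopes are a shared/independent Gaussian mixture achieving target
  correlation ρ per band (clipped at zero with κ = 0.4 modulation depth, so
  clipping is rare and realized envelope correlation stays within ±0.1 of
  target at 600 s). The sampling default is 250 Hz; any rate ≥ 128 Hz is
  accepted.
* **Determinism.** One root seed; every stream derives a child seed from a
  stable string hash (`child_seed()`), so adding participants or toggling
  stages never perturbs existing streams; generators are bit-reproducible.

What the generator does *not* emulate: PPG waveform morphology and beat
detection, ocular/muscle EEG artifacts and their ICA removal, volume
conduction or any head geometry, non-stationary session structure. Passing
tests therefore demonstrate that the statistics recover known coupling under
idealized noise, not that wearable data of this quality yield any particular
real-world effect size. Real-data values are not recoverable without the
original recordings; what must and does hold on synthetic
cohorts is the qualitative structure — ordered coupling yields ordered
group synchrony, nulls are centred, and operating characteristics
(artifact recall ≥ 80 %, false flags ≤ 5 %, mask calibration) meet their
targets.

## Numerical and design choices

* **Exact KS p-values.** The demographic normality screen uses the
  population-SD fit and the exact finite-sample Kolmogorov distribution
  (Marsaglia–Tsang–Wang), appropriate at n = 6; the asymptotic series is an
  option. No Lilliefors correction for estimated parameters is applied, to
  match the convention of the original analysis tooling.
* **Both SD conventions** (n and n−1) are first class in `describe_ages()`
  because demographic reports mix them; the mode used is recorded in the
  output.
* **Problem sizes.** Validation suites run at reduced scale chosen for
  statistical adequacy: dyad-session durations of 600 s (six full
  correlation windows), 3 sessions × 3–5 dyads per group for power checks
  (50 replicates), 30 replicates for null calibrations, EEG fixtures of 2–4
  channels at 128 Hz for 330–400 s. These sizes make each check's
  expected effect at least ~3 SE wide.
* **Ties and degenerate inputs.** Zero-variance windows and cells are
  skipped/flagged (`undefined`), not silently zeroed; empty overlaps return
  flagged no-value results rather than errors, since partially missing
  sessions are normal in this design.

## Running the pipeline

`run_pipeline()` executes simulate → preprocess → synchrony → EEG power →
sham mask → demographics with a nested configuration
(`default_run_config()`, YAML round-trip via `write_run_config()`), writing
TSV/CSV/JSON artifacts and a manifest of parameter hashes and output
checksums. Stages re-run only when their parameter hash or outputs change,
so the pipeline is incrementally re-runnable and byte-reproducible for a
given seed.

## Known limitations

* The corrector's interval-value replacements (isolated long/short rule) are
  not sum-preserving, so downstream beat times can drift by a few ms per
  correction; split/merge/recentre rules are exact.
* The sham-mask false-survival inflation at small ensembles (above) is
  inherent to the procedure, not fixed here.
* Band-power correlations on ~20 heavily smoothed points have few effective
  degrees of freedom; single-dyad maps are noisy by construction, which is
  precisely why the sham ensemble, not a parametric r-to-p formula, carries
  the inference.
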