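# triphasic

Analysis of evoked spiking dynamics in paired somatosensory (S1) and motor
(M1) cortex recordings, for experiments in which a brief (millisecond-scale)
peripheral photostimulus to the hand elicits a **triphasic** population
response: a short-latency peak, an interval of suppressed firing
(~110–170 ms), and a late rebound (~190–400 ms). The package is aimed at
systems neurophysiologists working with sorted spike trains from awake,
head-fixed preparations with linear probes in both areas, and at anyone who
needs a fully testable reference implementation of this analysis style.

## What it computes

For each active unit, spiking is binned in 5-ms bins aligned to stimulus
onset and averaged over trials into a PSTH spanning ±0.5 s, with baseline
statistics from the 250 ms before onset. A unit is **stimulus-responsive**
when the maximum of its z-scored PSTH exceeds 2.5 over the post-stimulus
half; the default z-score is variance-stabilised,

    z_b = ( sqrt(c_b) − sqrt(c_base) ) / (1/2),

with `c_b` the summed count in bin *b*, so that false-positive control and
detection power are independent of a unit's baseline rate (see the methods
vignette for why the naive baseline-s.d. z-score breaks down at ~1 Hz
baselines). Responsive units then get the triphasic decomposition:

* **peak**: amplitude = max baseline-subtracted rate in 0–100 ms; onset =
  left edge of the first bin of the supra-threshold (2.5 s.d.) run holding
  the peak; duration = onset to the first bin below 1 s.d.;
* **suppression** (110–170 ms) and **rebound** (max ±20 ms in 190–400 ms):
  per-trial window rates vs per-trial baselines, paired Wilcoxon signed
  rank at α = 0.05;
* laminar profiles in 20 bins of normalised cortical depth; PV/non-PV
  partitions from opto-tagging (short-latency, sustained laser responses vs
  sham); propagation speeds (distance/latency, averaged as mean of
  ratios); paired-pulse recovery ratios with Friedman + Dunn–Šidák;
  15–50 ms silencing-effect integrals with BH-corrected within-recording
  tests.

A synthetic-cohort generator (`simulate_cohort()`) emulates the whole
experiment — protocols, PV structure, laminar biases, paired-pulse recovery
and partial silencing — as inhomogeneous Poisson processes with retained
ground truth, so every estimator is validated by parameter recovery.

## Worked example

```r
library(triphasic)
co <- simulate_cohort(seed = 1)     # 13 paired S1+M1 recordings, 40 units/probe
an <- analyze_cohort(co)
print(an)
#> Cohort analysis: 1040 units on 26 included probes; 259 responsive
#>   S1: 35.8% responsive, onset 15.0 ms, amplitude 84.5 Hz
#>   M1: 14.0% responsive, onset 24.1 ms, amplitude 47.7 Hz
an$summary[1:3, c("parameter", "s1_mean", "s1_sd", "m1_mean", "m1_sd", "p_value")]
#>                       parameter s1_mean s1_sd m1_mean m1_sd p_value
#> 1     Baseline firing rate (Hz)    1.20  0.18    0.61  0.11 0.00024
#> 2 Stimulus-responsive units (%)   35.77  6.80   14.04  3.89 0.00158
#> 3            Onset latency (ms)   15.05  3.00   24.32  3.03 0.00024
round(an$speeds$onset$hand_s1_m_per_s[["mean"]], 2)   # hand -> S1, m/s
#> [1] 3.04
round(an$paired_pulse$S1$ratio_by_lag$ratio_mean, 2)  # 2nd/1st pulse at 150/250/350 ms
#> [1] 0.48 1.12 0.97
round(an$pv_partition$pv_spike_share_pct, 1)          # % evoked spikes from PV units
#> [1] 75.5
```

Reading the output: the pipeline recovers the generative S1 statistics —
36.7% responsive units with 1.2-Hz baselines, ~15-ms onsets, a ~20%
suppressed and ~30% rebounding subpopulation — from spike trains alone, and
the per-area contrast (delayed, attenuated, less often responsive M1) comes
out as designed. The paired-pulse ratio near 0.5 at the 150-ms lag is the
suppressed-interval excitability drop; PV interneurons carry about three
quarters of the evoked spikes. The detected M1 responsive fraction
(14% vs the generative 25.6%) reflects the information limit of detecting
~26-Hz, ~22-ms responses in 25 trials; the vignette quantifies this and the
other known estimator biases.

File-based workflows use `run_synth()` / `run_analyze()` / `run_report()`
(CSV tables in, CSV tables and a markdown report out), or the thin CLI
wrapper `inst/cli/triphasic.R` with subcommands `synth`, `analyze`,
`report`. `inst/extdata/silencing_reference.csv` ships the per-mouse
integrated-firing-rate reference table used to check the silencing-ratio
arithmetic.

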