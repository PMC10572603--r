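---
title: "Quantifying drug effects on compound nerve action potentials: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying drug effects on compound nerve action potentials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(napamyloid)
```

## The problem

An excised peripheral nerve in a perfusion bath, stimulated supramaximally,
produces a compound nerve action potential (NAP): the superposition of
thousands of single-axon potentials arriving at the recording electrodes
after conduction delays set by each axon's velocity. Amyloid-β 42 applied
to the bath depresses the NAP in a way that is non-monotonic in
concentration, develops over hours, and is most visible at low stimulus
currents and short inter-stimulus intervals (ISIs). `napamyloid`
re-implements the full quantification pipeline for such experiments —
waveform feature extraction, template registration, and the statistical
battery — together with a synthetic experiment generator, so that every
stage is testable without animal recordings (none are publicly deposited
for this design).

The simulated experiment follows the standard protocol: 112 nerves split
over 9 concentration groups (ordinal `CONC` 0–8; vehicle n = 40, 70 pM to
70 µM n = 8 each, 700 µM n = 16), 36 thirty-minute segments (`EXPTTIME`)
with the compound added at the start of segment 4, and two interleaved
seven-stimulus sets: set 0 increases current (1–15 mA, 4 ms ISI), set 1
shortens the ISI (166 ms down to 1 ms at 15 mA). Waveforms are sampled at
99 kHz and recorded ~1 cm from the stimulating electrodes.

## The synthetic-data generator

A nerve is `n_classes` axon classes with lognormal conduction velocities
(median 40 m/s, `sdlog` 0.35) and lognormal recruitment thresholds (median
3 mA, `sdlog` 0.5, making 15 mA supramaximal and 1 mA usually
sub-threshold). Each class contributes a biphasic unit potential — a
difference of two Gaussians, positive lobe (0.15 ms) before negative lobe
(0.30 ms), lobe ratio 0.6 — delayed by `distance / velocity`. A class
fires when the current exceeds its threshold, attenuated by an
availability factor `1 − exp(−ISI/τ_r)` (τ_r = 1 ms) that stands in for
residual sodium-channel inactivation. Three slow processes act
multiplicatively on amplitude:

* **Wallerian decline** `exp(−(j−1)/τ_w)` with τ_w = 60 segments, so a
  control nerve retains ~56% of its amplitude at segment 36 — the
  qualitative decline seen in excised-nerve preparations.
* **Drug effect** `1 − e(CONC)·ramp(j)`: the maximal fractional depression
  `e` is 0 in vehicle, rises through 6–25% to its maximum at `CONC` 4
  (70 nM) and falls to ≈1% at the highest doses; the logistic `ramp`
  (midpoint 6 segments after onset, width 2) reaches 95% within 10–15
  segments, i.e. 5–8 h — the stated onset dynamics.
* **Couplings**: the same latent effect elevates recruitment thresholds
  (`threshold_shift_gain`, so low currents are depressed more) and
  elongates τ_r (`refractory_gain`, so short ISIs are depressed more).
  Setting both gains to zero gives a purely multiplicative,
  amplitude-only effect — the case in which the waveform-correlation
  theory makes a sharp prediction (below).

Electrode placement varies across nerves through a lognormal gain
(`sdlog` 0.2), a lognormal electrode-distance factor (`sdlog` 0.08) and a
small constant offset; this is precisely the nuisance variation the
registration stage removes. A deterministic damped-oscillation stimulus
artifact occupies samples 0–9 only, so the zero-weight prefix of the
registration is exercised. Additive Gaussian noise has standard deviation
`noise_sd` (default 2%) of the nerve's baseline peak-to-peak amplitude.

Choices the protocol leaves open, fixed here once: the stored window is
512 samples (~5.17 ms), long enough to contain peak, trough and recovery
for velocities ≥ 10 m/s over 1 cm; the experiment is simulated at segment
granularity (one mean waveform per 30-min segment) because the analysis
uses only segment means; every nerve draws from a private RNG stream
derived by fixed hashing from the root seed, so subsetting nerves or
segments never changes another nerve's records.

What the generator does **not** emulate: biophysical (Hodgkin–Huxley)
membrane dynamics, temperature or perfusion chemistry, true sweep-to-sweep
variability within a segment, non-stationary noise, or electrode drift
within an experiment. A green test therefore establishes that the
*analysis machinery* behaves as specified on data with the assumed
statistical structure — not that the biology is as modelled.

## Feature extraction

Twelve descriptors per NAP. The baseline is the mean of the ten samples
immediately after the artifact region (the protocol never defines
"baseline" for the recovery half-level; a pre-response window is the least
biased choice). The peak is the post-artifact maximum, the trough the
minimum after the peak, ties broken by the earliest sample; fixed-offset
amplitudes use 0.08 ms (rise/decline) and 0.16 ms (recovery), which are
7.92 and 15.84 samples at 99 kHz — voltages are linearly interpolated at
fractional indices, never rounded. Half-level latencies come from linearly
interpolated crossings: decline = first downward crossing of
(peak+trough)/2 after the peak; rise = last upward crossing before the
peak; recovery = first upward crossing of trough/2 after the trough. A
recovery level never reached inside the window yields a missing value
(degenerate, hard-to-mark troughs propagate as excluded cases, not
zeros). Rise/decline/recovery amplitudes are reported as positive
magnitudes; the verbal definition leaves the sign ambiguous. The stimulus
response ratio (SRR) divides each peak-to-peak amplitude by the last
(largest-current) stimulus of set 0 or the first (longest-ISI) stimulus of
set 1. All parameters are normalized per (nerve, set, SEQ) by their
segment-3 value, the last pre-drug segment, and only segments 4–36 enter
the analyses.

## Template registration

Per (nerve, set, SEQ), the transform `w*(i) = a·w(b·i + c) − d` is fitted
once against the first-segment waveform of an exemplar nerve (default: the
lowest nerve id) by minimizing the weighted mean-square difference, and
then applied unchanged to all segments — removing placement differences
while leaving within-nerve dynamics untouched. Numerical choices:

* Weights: 0 for the first 10 samples, 1 to sample 100, then an
  exponential taper (`exp(−(i−100)/20)`); the taper form and its 20-sample
  constant are a choice, the protocol requires only a fast approach to
  zero.
* The printed objective compares the template with itself (both subscripts
  name the exemplar); it is implemented as template versus the registered
  n-th nerve — the only reading consistent with its purpose — and divided
  by the number of points, which does not move the argmin.
* Interpolation clamps to edge values outside the window, avoiding fake
  discontinuities at small latency shifts; Nelder–Mead from
  `a = pp(template)/pp(waveform)`, `b = 1`, `c = 0`, baseline-matched `d`;
  relative tolerance 1e-10, at most 500 iterations. Zero-amplitude
  waveforms are unregistrable (error), as are fits ending with `a, b ≤ 0`.

On waveforms constructed from the template with known parameters, the fit
recovers a and b within 1% and c within 0.5 samples noise-free, and a
within 5% at 1% amplitude noise across 100 seeds (the acceptance bands,
verified in `test-acceptance.R`; observed errors are typically an order of
magnitude smaller).

## Statistical battery

* **Endpoint tests** (segment 36, first stimulus of set 1): one-way ANOVA
  of each normalized descriptor over the 9 groups (df 8, 103 at full
  design) at the Bonferroni level 0.05/12 ≈ 0.004, confirmed by
  Kruskal–Wallis at 0.1/12 ≈ 0.008, plus OLS on `CONC` and `CONC²` (the
  ordinal 0–8 as the regressor, matching the original coding) to capture
  the U-shaped dose response.
* **Repeated measures**: split-plot ANOVA with `CONC` between nerves and
  `EXPTTIME` plus ISI (7 levels) or current (6 levels — the 1 mA stimulus
  is dropped as frequently sub-threshold, matching the stated six
  intensities) within nerves, restricted to `CONC ≤ 4` where the dose
  response is monotone. The protocol text is inconsistent about this
  subset ("≤ 0.70 nM" in one place, "≤ 70 nM" elsewhere); ordinals 0–4
  (≤ 70 nM) are the default, configurable via `conc_subset_max`. The
  decomposition is computed from cell means (exact for panels balanced
  over the within factors, which is enforced — missing cells error rather
  than being imputed) because `aov` with `Error()` strata is far too slow
  inside power loops; it is verified against `aov` in the tests.
  Sphericity corrections are not applied (none are used in the source
  design).
* **Correlation screening**: Spearman rank correlation of every
  (descriptor, SEQ, EXPTTIME) cell against `CONC` over the low
  concentration subset, using the t approximation throughout (`CONC` is
  heavily tied, exact p-values are unavailable anyway). The BH step-up
  controls FDR at 0.05 over the widest natural family — all
  12 × 7 × 33 tests of one stimulus set (the family is not stated in the
  protocol; a per-EXPTTIME family would be less conservative); the screen
  is repeated with raw p < 0.01. Counts of significant segments form the
  12 × 7 table whose parameter × SEQ independence is tested by χ² on
  df = 66. Note this test detects *interaction*: a single affected row
  spread uniformly over stimuli is a null table for it.
* **Waveform maps**: per-sample Spearman R and p of registered voltage
  against `CONC` (ordinals 0–4), with raw-p and BH masks per slice. If
  the drug only scales amplitude, |R| must track the template's |voltage|;
  this comparison is made over the support of the registration weights
  (`v_i > 0.01`), because beyond the taper both profiles are pure noise
  and the rank correlation is diluted (~0.62 over the full window versus
  ~0.93–0.97 over the support in amplitude-only simulations). |R| rather
  than signed R is used since an amplitude effect drives the trough as
  strongly as the peak; both conventions are available. Clustering of
  significant samples over time is tested by a uniformity χ² over 8
  equal-width post-artifact bins, halving the bin count until expected
  counts reach 5. Maps can be computed at every segment or only at the
  final one; both modes are exposed.

## Calibration and power, as verified by the tests

Under the null generator (no drug effect) the endpoint ANOVA at level
0.004 rejects in well under 1% of 1000 replicates for every descriptor
(SRR is calibrated at SEQ 2, being identically 1 at the reference
stimulus), and the pointwise Spearman raw-p < 0.01 rate is ≈1%. With the
default effect profile, the argmin of end-of-experiment group means lands
on `CONC` 4 in ≥90% of 200 replicates, the `CONC × ISI` interaction is
detected in ≥80%, the three amplitude descriptors carry the largest
count-table rows, and the |R|-vs-voltage profile correlation exceeds 0.9
for amplitude-only effects. Monte-Carlo blocks run at reduced resolution
(256-sample windows, 64 axon classes, thinned segment grids) purely for
runtime; thresholds and replicate counts are never scaled.

## Known limitations

Registration is a local simplex fit from one deliberate initialization —
no multi-start or annealing — and assumes the affine time map is adequate;
strongly shape-changing effects would demand nonlinear warping, which is
out of scope. The independence χ² uses the fixed nominal df even when
table margins are sparse. The generator's availability factor is a
one-time-constant caricature of sodium-channel recovery; it produces the
right orderings (amplitude non-decreasing in ISI and current) but not
quantitative refractory curves. p-values from the Spearman t approximation
are approximate for n ≤ 10 per slice.
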