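# napamyloid

Quantification of drug effects on compound nerve action potentials (NAPs),
built around the in-vitro peripheral-nerve assay in which amyloid-β 42 is
bath-applied to excised sciatic nerve: a seeded synthetic-experiment
generator, automated waveform feature extraction, four-parameter template
registration, and the downstream statistical battery (endpoint ANOVA /
Kruskal–Wallis / quadratic dose regression, repeated-measures ANOVA over
stimulus factors, BH-FDR Spearman screening with significance-count tables
and χ² tests, and pointwise correlation maps along the waveform). It is
intended for electrophysiologists and biostatisticians who want the whole
analysis chain reproducible on synthetic data with the same design: 112
nerves over 9 concentration groups (ordinal `CONC` 0–8), 36 thirty-minute
segments (`EXPTTIME`, compound added at segment 4), and two interleaved
seven-stimulus sets (increasing current 1–15 mA; shortening ISI 166–1 ms),
sampled at 99 kHz.

## Core models

**Simulator.** A nerve is a population of axon classes with lognormal
conduction velocities and recruitment thresholds; each class contributes a
biphasic unit potential delayed by conduction time. The stored waveform at
segment *j* for a stimulus of current *I* after inter-stimulus interval
ISI is

    w(t) = Σ_c  1[θ_c ≤ I] · (1 − e^(−ISI/τ_r)) · k(t − d/v_c) · A_n(j) + artifact + noise
    A_n(j) = g_n · e^(−(j−1)/τ_w) · (1 − e(CONC) · ramp(j))

with Wallerian time constant τ_w, a non-monotonic dose profile `e(CONC)`
maximal at `CONC` 4 (70 nM), and a logistic onset `ramp` saturating 10–15
segments after drug onset. The same latent effect can elevate thresholds
and elongate τ_r, making low currents and short ISIs more sensitive.

**Registration.** Waveforms are normalized per (nerve, set, SEQ) against an
exemplar nerve by fitting `w*(i) = a·w(b·i + c) − d` (amplitude, time
scale, latency shift, offset) to minimize the weighted mean square
difference `I = Σ_i v_i [w_template(i) − w*(i)]² / n_p`, with weights
`v_i = 0` over the first 10 samples (stimulus artifact), 1 through sample
100, then an exponential taper.

**Statistics.** Twelve descriptors per NAP (amplitudes, velocity,
duration, half-level latencies, fixed-offset slopes, recovery measures,
stimulus response ratio), normalized to segment 3. Endpoint ANOVA across
`CONC` at the Bonferroni level 0.05/12 ≈ 0.004 (df 8, 103 at full design),
Kruskal–Wallis at 0.1/12 ≈ 0.008, OLS on `CONC` and `CONC²`; split-plot
repeated-measures ANOVA (between: `CONC`; within: `EXPTTIME` × ISI or
current); Spearman screening of every (descriptor, SEQ, EXPTTIME) cell
against `CONC ≤ 70 nM` with Benjamini–Hochberg FDR < 0.05, summarized in
12 × 7 significance-count tables tested by χ² on df = 66; and per-sample
Spearman maps over registered waveforms with |R|-vs-voltage profile
correlations and time-point χ² tests.

## Worked example

A scaled-down experiment (30 nerves, 12 segments, 256-sample windows) runs
the whole pipeline in well under a minute:

```r
library(napamyloid)
cfg <- default_config()
cfg$design <- list(n_nerves = c(6, 3, 3, 3, 3, 3, 3, 3, 3), n_segments = 12,
                   window_samples = 256)
cfg$population <- list(n_classes = 60, noise_sd = 0.02)
rep <- run_nap_pipeline(cfg, seed = 42)

rep$endpoint[1, ]          # endpoint tests for peak-to-peak amplitude
#> F = 41.23 (df 8, 21), p = 3.95e-11;  H = 25.17, p = 0.00145
rep$quadratic
#>        term     estimate            p
#>   intercept  0.871875053 1.217011e-33
#>        CONC -0.057562741 9.108951e-09
#>       CONC2  0.007525627 5.181061e-09
rep$flags
#> $significant_concentration_effect TRUE;  $min_amplitude_conc 4
rep$waveform$seq1$profile_rho
#> 0.863
```

Reading: the end-of-experiment peak-to-peak amplitude differs across
concentration groups far beyond the 0.004 Bonferroni level; the quadratic
term is positive (U-shaped dose response) and the group-mean amplitude is
minimal at `CONC` 4 (70 nM), i.e. the configured non-monotonic effect is
recovered; the pointwise Spearman |R| profile tracks the NAP voltage
profile (ρ = 0.86 here), the signature of a predominantly amplitude-scaling
effect. At the full 112-nerve design the endpoint F carries df (8, 103).

Individual stages are plain functions: `simulate_experiment()`,
`features_table()` / `normalize_to_baseline()`, `register_dataset()`,
`endpoint_anova()` / `repeated_measures()` / `build_count_table()`,
`pointwise_spearman()` / `r_vs_voltage_profile()` / `timepoint_chi2()`.
A CLI wraps them:

```sh
Rscript -e 'napamyloid::nap_cli()' run --config cfg.json --seed 17 --out results/
Rscript -e 'napamyloid::nap_cli()' simulate --seed 17 --out data/
```

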