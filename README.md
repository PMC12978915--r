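# emgmap

Multimuscle surface-EMG (sEMG) strain mapping for structured imaging
protocols, built around the mammography positioning protocol: two
craniocaudal (CC) and two mediolateral-oblique (MLO) breast compressions,
performed with a flat and a curved paddle, bracketed by resting control
recordings (C1, C2, C3). Seven muscles are monitored bilaterally
(sternocleidomastoid, upper trapezius, deltoid, infraspinatus, teres
major, serratus anterior, external oblique - 14 channels), and the
package quantifies which muscles a compression strains, on which side,
and by how much.

## What it computes

Starting from raw multichannel sessions (CSV, long or wide layout, default
sampling rate 1925.925 Hz):

1. **Preprocessing** - trim 1.5 s from each segment edge; zero-phase
   4th-order Butterworth bandpass 20-500 Hz; divide every channel by the
   standard deviation of its reference control's 250 ms RMS envelope
   (flat-paddle segments reference C2, curved-paddle segments C3).
2. **Feature bank** - per (channel, segment), five time-domain metrics
   (meanRMS, stdRMS, slope-sign-change and zero-crossing rates, waveform
   length `WFL = sum |x_{i+1} - x_i|`) and five frequency-domain metrics
   from a Welch PSD (128-sample Blackman window, 50% overlap): mean and
   median frequency, normalised spectral entropy, high-frequency power
   fraction DP (share of in-band power at >= 150 Hz), and spectral
   deformation `SpecDef = Omega_2 / Omega_1`, with
   `Omega_r = (M_r / M_0)^{1/r}`, `M_r = sum f_k^r P_k`.
3. **Contrasts** - paired t tests across participants for four families
   (each compression vs its reference control, flat vs curved paddle,
   CC vs MLO angle, control vs control), Kolmogorov-Smirnov (Lilliefors)
   normality screening, Bonferroni correction (m = 8 / 4 / 4 / 2).
4. **Summaries** - mean (SD) group tables with significance marks, a
   muscle-by-metric sensitivity matrix (fraction of the 8 compressions
   significant), and a per-view absolute percent-change activation map.
5. **Simulation** - a seeded generator of protocol-structured synthetic
   cohorts (spectrally shaped Gaussian baseline, ipsilateral gains with
   a low-frequency narrowband admixture, lognormal between-participant
   variability) so the full pipeline is testable without recordings.

## Worked example

```r
library(emgmap)

cfg  <- sim_config(n_participants = 8, fs = 512,
                   control_duration_s = 3, compression_duration_s = 3,
                   seed = 7)
pre  <- preprocess_params(trim_s = 0.5, band_high_hz = 245)
psd  <- psd_params(band_high_hz = 245)

cohort <- simulate_cohort(cfg, activation_map())
norm   <- emg_cohort(lapply(cohort$sessions,
                            function(s) preprocess_session(s, pre)$session))
feat   <- extract_cohort_features(norm, pre, psd)
cc     <- run_family(feat, "compression_vs_control")
sensitivity_matrix(cc)["deltoid_left", c("meanRMS", "stdRMS", "SpecDef")]
#> meanRMS  stdRMS SpecDef
#>   0.500   0.375   0.000
pcm <- percent_change_map(feat)
subset(pcm$max_pct, muscle == "deltoid" & metric == "meanRMS")
#>     muscle  metric  max_pct
#> 22 deltoid meanRMS 382.2945
subset(pcm$max_pct, muscle == "serratus_anterior" & metric == "meanRMS")
#>               muscle  metric max_pct
#> 25 serratus_anterior meanRMS 1.849934
```

The deltoid meanRMS sensitivity is 0.5: with the default activation map
the deltoid responds to its 4 ipsilateral compressions out of 8 total,
exactly the lateral clustering the method is designed to expose. Its
meanRMS percent change is near the construction value
`100 * (gain - 1) = 300%` for the default deltoid gain 4 (here 382% -
an 8-participant cohort with lognormal gain variability). The inactive
serratus anterior stays below 2%. (This demo uses a small, short-segment
cohort; frequency-metric contrasts like SpecDef need the default 25
participants to reach significance reliably.)

A JSON-configured driver writes the full artifact set (`features.csv`,
`comparisons.csv`, `sensitivity_matrix.csv`, `percent_change.csv`,
`group_table.csv`, `manifest.json`):

```r
run_pipeline(list(simulate = list(seed = 7)), out_dir = "artifacts")
```

or from the shell: `Rscript inst/cli/emgmap.R run --seed 7 --out artifacts`.

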