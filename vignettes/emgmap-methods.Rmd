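---
title: "Methods: multimuscle sEMG strain mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimuscle sEMG strain mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

A mammogram forces the patient into a sustained, asymmetric posture:
one arm extended along the imaging table, chest held parallel to it,
head turned away from the face shield, trunk rotation blocked. `emgmap`
quantifies the muscular cost of that posture from surface EMG recorded
over seven muscles bilaterally (14 channels) across a structured
protocol: a large-room control (C1), an examination-room control (C2),
four 15 s flat-paddle compressions (right/left craniocaudal, left/right
mediolateral oblique), a third control at the paddle change (C3), and
the four compressions again with a curved paddle. Controls are 2 min;
compressions 15 s; the default sampling rate is the vendor's
1925.925 Hz, stored per session and never assumed by downstream code.

## Preprocessing model

Each segment is trimmed by 1.5 s at both ends (floor-rounded to whole
samples) to drop start/stop misalignment artifacts, then filtered with a
4th-order Butterworth bandpass, 20-500 Hz. The filter is applied
forward-backward (zero phase), so the effective attenuation order
doubles; we read the stated "fourth order" as the designed order, which
is the convention of the major toolboxes. The design was verified
coefficient-by-coefficient against an independent reference
implementation.

Amplitude normalisation divides every channel by the sample standard
deviation of the RMS envelope (250 ms rectangular windows, 50% overlap)
of that channel's *reference control*: C2 for flat-paddle segments and
for C2 itself, C3 for curved-paddle segments and itself. C1 borrows C2's
scale so that control-vs-control contrasts remain meaningful. Two
consequences anchor the test suite:

* the stdRMS feature of a normalised reference control is exactly 1
  (up to ~1e-15 float jitter), which is why group tables print control
  stdRMS as "1" with an SD around 1e-15 - the structure a published
  group table of this pipeline shows; and
* all frequency-domain metrics are invariant under normalisation, while
  amplitude metrics scale by 1/s.

The envelope window (250 ms) is our choice - conventional for postural
sEMG and exposed in `preprocess_params()`; the normalisation convention
(std of the reference control envelope) is the only simple rule we found
that forces the control stdRMS column to exactly 1 while leaving control
meanRMS a free, near-constant value. Both are documented inferences, not
settings copied from a protocol.

## The ten metrics

Time domain, per trimmed, normalised segment: mean and standard
deviation of the RMS envelope (meanRMS, stdRMS); zero crossings and
slope sign changes, counted with optional amplitude thresholds
(defaults 0) and divided by segment duration so unequal-length segments
are comparable; and waveform length, the total variation
`WFL = sum |x[i+1] - x[i]|` over the whole segment.

WFL deliberately follows the per-segment definition despite its duration
dependence: published group tables for this protocol show control and
compression WFL of the same order of magnitude although the segments
differ 10-fold in length, so the upstream convention cannot be
reconstructed with certainty. The consequence - WFL contrasts are only
meaningful between equal-duration segments - is handled in the test
world by simulating equal control/compression durations, and flagged
here as a known limitation for real data.

Frequency domain, from a Welch PSD (128-sample Blackman window, 50%
overlap, mean-removed tapered segments, one-sided density scaling):

* meanFreq - spectral centroid of the in-band (20-500 Hz) power;
* medianFreq - half-power frequency, interpolated linearly inside the
  crossing bin with each bin's power spread over its interval, so a pure
  line spectrum's median is the line frequency itself;
* entropy - Shannon entropy of the normalised in-band spectrum divided
  by log(K), in [0, 1];
* DP ("drop in power") - the fraction of in-band power at or above a
  configurable 150 Hz split. No formula is published for this metric;
  a high-frequency power fraction is the simplest statistic that
  *decreases* under the downward spectral shift that sustained
  contraction produces, matching the reported direction of change;
* SpecDef (spectral deformation) - the normalised spectral-moment ratio
  `Omega_2/Omega_1`, `Omega_r = (M_r/M_0)^(1/r)` with
  `M_r = sum f^r P(f)`. This is the only standard sEMG quantity
  consistent with the printed unitless "Omega/Omega" values of roughly
  1.0-2.3; it equals 1 exactly for a line spectrum (Jensen's inequality
  gives >= 1 always) and grows with spectral spread. Both DP and SpecDef
  are documented inferences.

## Contrast families and inference

For each (muscle, metric), paired t tests across participants compare:
each of the 8 compressions with its reference control (Bonferroni
m = 8 - the family size the protocol's own description fixes); flat vs
curved paddle per view (m = 4); CC vs MLO per breast within paddle
(m = 4); and C1 vs C2 / C1 vs C3 (m = 2). The m = 4/4/2 sizes are by
analogy, configurable, since the upstream correction scope for the minor
families is not stated. Significance is adjusted p < 0.05.

Normality of the paired differences is screened with a
Lilliefors-corrected Kolmogorov-Smirnov test (Dallal-Wilkinson
approximation with the Stephens branch above p = 0.1). It is advisory:
every comparison carries `ks_p`, but the t test is always computed,
because no gating rule is documented. Zero-variance differences (which
occur by construction, e.g. stdRMS between two normalisation-forced
controls) yield p = 1 and a `degenerate` flag rather than an error.

The sensitivity matrix is the per-(muscle, metric) fraction of the 8
compression contrasts that were significant. The percent-change map
pools flat+curved compressions per view and C2+C3 as control, and
reports `|mean_comp - mean_ctrl| / |mean_ctrl| * 100`; pooled means are
used rather than averaging per-participant ratios because near-zero
per-participant control means would destabilise the latter (the upstream
pooling arithmetic is not stated; the alternative is one code line away
in `percent_change_map`).

## What the simulator emulates - and what it does not

`simulate_cohort()` generates baseline noise as Gaussian processes
shaped to the classical two-parameter analytic sEMG spectrum
`P(f) = fh^4 f^2 / ((f^2+fl^2)(f^2+fh^2)^2)` (defaults fl = 60,
fh = 120 Hz), scaled to 0.02 mV. During a compression, channels
ipsilateral to the compressed breast are multiplied by a muscle-specific
gain (defaults: deltoid 4.0, infraspinatus 2.0, trapezius 1.9,
sternocleidomastoid 1.8, teres major 1.6, serratus anterior and external
oblique 1.0 - the deltoid-dominant ordering the group tables motivate)
and 30% of their power is replaced by a narrowband 70 +/- 5 Hz
component. The admixture is the minimal mechanism that reproduces the
reported *decrease* of meanFreq, medianFreq, DP and SpecDef under
activation: pure frequency-axis scaling would leave SpecDef invariant,
and a pure gain changes no frequency metric at all.

Between-participant variability is a lognormal multiplier (mean 1,
CV 0.3) on the *excess* gain, `g_p = 1 + (g - 1) L`. Multiplying the
gain itself would make inactive (gain-1) channels vary between
participants, contradicting both the contralateral-gain-of-1 rule and
the requirement that an all-ones gain map be exactly indistinguishable
from the control state. Seeding is hierarchical (root seed, participant
substream, segment substream), so cohorts are reproducible and a
participant's data is invariant to cohort size. Noise is generated at
the next 2-3-5-smooth FFT length and truncated, purely for FFT speed.

The simulator does *not* model: motor-unit physiology, force-EMG
coupling (compression forces are not modelled at all), breath-hold or
tremor, nonstationary bursting of real resting EMG, electrode artifacts,
or ECG contamination. Consequently a green simulation test establishes
that the *pipeline arithmetic* behaves as designed (calibration, gain
recovery, laterality), not that real recordings will show the same
effect sizes. In particular, real control envelopes are far more
variable relative to their mean than the simulator's stationary noise,
so simulated meanRMS values are not comparable in magnitude to published
ones (the normalisation makes stdRMS, not meanRMS, the anchored
quantity).

## Numerical choices

* Zero-phase filtering uses odd-extension padding (min(n-1,
  ceil(6 fs / f_low)) samples) with a constant-prehistory start; for a
  bandpass whose taps sum to zero this is the exact steady state, so a
  constant input yields an exactly zero output.
* Trimming floors to whole samples; envelope and Welch windows that do
  not fit completely are dropped, never padded.
* Welch segments are mean-removed before tapering (constant detrend);
  the Blackman taper is periodic, matching the reference implementation
  the tests freeze values from.
* ZC/SSC thresholds default to 0 (pure sign logic) and are exposed.
* Degenerate inputs fail loudly with named channels/segments: silent
  segments (zero in-band power), zero-variance control envelopes,
  too-short segments.
* Compression segments shorter than 5 s are rejected outright;
  durations outside +/-10% of the protocol's nominal values warn.

## Scaled test world

The Monte-Carlo acceptance checks (type-I calibration over 200 null
cohorts; fingerprint recovery over 100 activated cohorts, n = 25 each)
run at a reduced scale fixed once in the test helpers: fs = 512 Hz, band
20-245 Hz, 3 s segments with 0.5 s trim, *equal* control and compression
durations (see the WFL note above). At this scale one cohort's full
pipeline takes ~2 s, keeping the suite inside a CI budget while
exercising every stage end to end. The per-contrast null rate and the
per-cell family-wise rate are calibration properties independent of
segment length, which is what makes the reduction legitimate for those
criteria.

## Known limitations

* DP and SpecDef definitions are reconstructions; alternative published
  variants exist and would change absolute values (not directions).
* WFL is duration-dependent by definition; compare equal-length
  segments only.
* The Bonferroni family sizes for the paddle/angle/control families are
  by analogy, not documented upstream.
* The percent-change map's pooled-mean arithmetic is one of two
  plausible conventions.
* Edge transients make trim-then-filter and filter-then-trim differ by
  ~1% RMS on 120 s segments and ~2% on 15 s segments; the pipeline
  fixes the order (trim, filter, normalise).
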