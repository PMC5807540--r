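---
title: "Quantifying sleep spindles, slow waves and their group topographies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying sleep spindles, slow waves and their group topographies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

somnotype implements a complete quantitative pipeline for whole-night
multichannel sleep EEG: signal conditioning, artifact rejection, spectral
estimation, automated spindle and slow-wave detection, sleep-architecture
scoring, and nonparametric group statistics over electrode topographies.
This vignette is the package's account of the underlying methods: what each
stage computes, which choices were genuinely open and how they were
resolved, and what the validation suite does and does not demonstrate.

## The analysis pipeline

### Signal conditioning

`preprocess_recording()` applies, in order: a zero-phase 0.1 Hz high-pass,
resampling to 128 Hz, a zero-phase 0.5–40 Hz band-pass, and re-referencing
to the instantaneous scalp average.  All filters are 4th-order Butterworth
designs applied with zero phase.  Rather than running a forward and a
backward IIR pass per channel, the package multiplies the spectrum by the
squared magnitude response of the design — the exact transfer function of
forward–backward filtering — in the frequency domain.  This is
mathematically equivalent away from the record edges (it matches
`signal::filtfilt` to ~1e-10 on interior samples; the edge treatment is
circular rather than reflective), and it lets all channels and all
downstream bands share one FFT, which matters for the simulation-based
validation below.  On multi-hour records the edge difference affects a few
seconds at each end, which whole-night epoch masks render irrelevant.

A caveat on the average reference: subtracting the montage mean is standard
for high-density nets, where any focal source contributes little to the
common mode.  At low channel counts the montage mean contains a large
fraction of any spatially coherent signal, and re-referencing removes it.
`preprocess_recording(rereference = FALSE)` keeps the recorded reference;
the reduced-channel simulations in the test suite use that option (see
below), while full-density studies keep the default.

### Artifact rejection

`reject_artifacts()` computes, per channel and per 30-s NREM epoch, Welch
band power in 0.8–4.48 Hz and 20–30 Hz, and rejects an epoch on a channel
when either power exceeds a multiplier of that channel's mean over NREM
epochs.  Two open choices, both exposed as parameters:

* the multiplier is not dictated by the semi-automatic procedure the
  pipeline models; the default is 4.0 in both bands;
* rejection is per channel (a mask, not epoch deletion), so a local
  electrode artifact does not discard the epoch scalp-wide.  Downstream
  metrics use each channel's own retained time.

### Spectral estimation

`welch_psd()` splits each retained 30-s epoch into five non-overlapping 6-s
segments, Hamming-windows each, and averages periodograms within and across
epochs — a 1/6 Hz (0.1667 Hz) frequency grid at 128 Hz.  The one-sided
density is normalized so that the integral over frequency recovers the
signal variance; the test suite asserts Parseval's identity for sinusoids
to within 5% and spectral flatness for white noise.  `band_power()`
integrates bins whose centers fall in a half-open band.  Group comparisons
of band power default to log10 values (a skew reduction switchable to raw).

### Spindle detection and ISAs

`sigma_envelope()` band-passes each channel to 11–16 Hz and rectifies it.
The detector thresholds of `detect_spindles()` are *relative*: the lower
threshold is 2x and the upper 8x the channel's mean rectified amplitude
over the analyzed NREM samples, recomputed for each analysis window so that
thresholds are internal to the analyzed data.  An amplitude fluctuation
exceeding the upper threshold marks a spindle; its start and end are the
nearest points before and after the peak where amplitude drops below the
lower threshold; events sharing bounds are merged and events shorter than
0.25 s are discarded.

One representational choice deserves emphasis.  The rectified trace of an
oscillatory burst touches zero near every carrier zero crossing, so a
sample-by-sample threshold scan of the *raw* rectified signal would exit
the event every half cycle and no detection could survive the 0.25-s
minimum.  The amplitude time series the detector scans is therefore the
upper envelope of the rectified signal (linear interpolation through its
local maxima), which tracks the burst amplitude between carrier peaks; the
threshold *levels* remain factors of the mean rectified amplitude.  This is
the only reading under which the detector's defining properties hold
simultaneously: a constant sinusoid of amplitude a is never detected (its
envelope maximum a is below 8 x 2a/pi), while a burst peaking at 8.5x the
mean rectified amplitude is.  `sigma_envelope(method = "rectify")` exposes
the raw rectified series.

Event frequency is estimated from zero crossings of the band-passed
(unrectified) signal within the event; events are reported in the whole
(12–16 Hz), slow (12–14 Hz) and fast (14–16 Hz) ranges, with 14 Hz assigned
to the fast range so the sub-ranges partition the whole.

Integrated spindle activity is, per channel,

ISAs = sum over events of [ (integral of the amplitude envelope over the
event) / event duration ] / analyzed NREM minutes,

i.e. the sum of event mean amplitudes per analyzed minute (µV/min).  It
rises with spindle number, amplitude and duration at fixed analyzed time; a
single rectangular-envelope event of mean amplitude 10 µV in 10 analyzed
minutes gives ISAs = 1 µV/min exactly, which the suite asserts.  The
integral uses the raw envelope, not the supra-threshold excess; the
alternative is a flag.

### Slow-wave analysis

`detect_slow_waves()` follows the period-amplitude tradition: after a
zero-phase 0.5–4 Hz band-pass, every negative half-wave between two
interpolated zero crossings whose duration lies in 0.25–1.0 s is an event,
with no amplitude criterion by default — amplitude is the outcome under
study, not a filter (a microvolt criterion is available via `min_npamp`).
Parameters per event: NPAMP (most negative sample), average down-/up-slope
(|NPAMP| over time from the down-crossing to the peak / peak to
up-crossing), and maximal down-/up-slope (maximum |first-difference
derivative| after a centered 50-ms moving average, on the falling / rising
segment).  Half-waves straddling mask boundaries are discarded.  The band
and duration window are assumptions of this implementation (the tradition
it models defers them to earlier work) and are configurable; `band = NULL`
skips the internal filter for already band-limited input — useful because
a two-pass 0.5 Hz high-pass measurably attenuates an isolated half-wave
(its spectrum extends below 0.5 Hz), which is a property of the filter, not
of the measurement definitions.

### Sleep architecture and cycles

`score_architecture()` computes TST, sleep latency, WASO (wake between
onset and the final awakening; trailing wake is excluded from WASO but kept
in the efficiency denominator, matching the convention in which WASO and
efficiency are reported separately), efficiency, REM latency and stage
percentages of TST.  `detect_cycles()` applies the classical rule — a NREM
period of at least 15 min followed by a REM period of at least 5 min, the
REM minimum waived for the first cycle, REM episodes separated by under
15 min merged — with both thresholds configurable.  First-cycle stage
percentages are reported as percent of TST by default (percent of cycle
duration is a switch), since the convention behind the published tables
this mirrors is not stated.

### Group statistics

`unpaired_t()` is the pooled-variance two-sample t; `t_from_summary()`
reproduces t-tests from published mean ± SE rows with Welch–Satterthwaite
degrees of freedom; `spearman_corr()` uses average ranks and the t
approximation.  `snpm_cluster_test()` implements supra-threshold cluster
inference: channels with |t| above a cluster-forming threshold (default:
the two-tailed critical t at alpha = 0.05 for the design's df, 2.042 at
df = 30) form adjacency-connected clusters separately by sign; each
cluster's statistic is referred to the permutation distribution of the
maximal cluster statistic over random relabelings of group membership, the
original labeling always included, giving family-wise-corrected p-values.
Design choices:

* cluster statistic defaults to mass (sum of |t|); size is available — the
  original supra-threshold literature used size, and the source of the
  workflow does not say which;
* the relabeling count defaults to 8192; the acceptance simulations use the
  1024 the calibration experiment prescribes, and exhaustive enumeration is
  available for tiny designs.  A fixed full enumeration of two-sample
  relabelings is infeasible at 16+16 (C(32,16) ≈ 6x10^8);
* electrode adjacency is not part of the modeled workflow's description;
  the default is the distance rule with radius 1.3x the median
  nearest-neighbor distance, robust on irregular nets, with Delaunay
  triangulation of the 2D projection as the alternative.

## The synthetic-data generator

`generate_recording()` layers, per channel:

* **background**: spectrally shaped 1/f^alpha Gaussian noise, flattened
  below 0.5 Hz, with per-stage RMS (defaults 15/20/25/35/15 µV for
  W/N1/N2/N3/REM) and exponent (1.0 in wake and REM, 1.5 in NREM) — the
  classical steepening of the sleep spectrum with controllable band power;
* **spindles** in N2/N3: Hann-enveloped sinusoid bursts (frequency
  N(13.5, 0.6) Hz, duration ~1.0 ± 0.15 s, density 2.5/min in N2 and
  1/min in N3), with one amplitude draw per event projected through a
  topographic gain peaking at a centroparietal channel;
* **slow waves** in N2/N3: isolated negative half-sine deflections
  (duration 0.3–0.9 s, negative peak ~80 µV) with a frontal gain maximum —
  the half-sine form makes NPAMP and slope ground truth analytic;
* **artifacts**: broadband high-power whole-epoch bursts at 2/h with 6x the
  stage RMS, which the rejection stage must remove;
* log-normal event-level and subject-level variability on amplitudes and
  densities (CVs of 10–25%, see `synth_config()`).

`generate_hypnogram()` is a semi-Markov chain over the five stages with
geometric dwell times, an initial wake bout, and REM transitions blocked
before a configurable latency.  `stationary_stage_fractions()` gives the
chain's long-run stage fractions; Monte-Carlo stage percentages over 200
nights agree with them to within a few points (the REM-latency block and
the initial wake bias finite nights slightly, which the test tolerance
covers).

Two-group cohorts (`generate_cohort()`) share densities between groups and
apply multiplicative deficits in group B: `spindle_amp` scales the spindle
envelope; `sw_amp` scales the inserted slow waves *and* the background
amplitude below 4.5 Hz.  Scaling the delta background uniformly across the
0.5–4 Hz detection band reduces measured NPAMP and slopes while leaving
the band-limited signal's zero-crossing rate — hence detected slow-wave
density — unchanged, exactly the deficit pattern the generator is meant to
emulate.

**The detector-saturation choice.**  The spindle envelope peak defaults to
260 µV at the topographic maximum, with a gain profile of the form
floor + (1 − floor)·Gaussian (floor 0.65).  Relative to the synthetic
sigma-band background this places spindle amplitude at roughly 1.7–2.7x
the 8x-mean detection threshold on every channel, in both groups, even
under a 30% amplitude deficit.  This is deliberate: a relative-threshold
detector translates amplitude shifts into detected-density shifts wherever
amplitudes straddle the threshold, and the effect pattern under study —
reduced integrated spindle activity with preserved density and duration —
presupposes detection operating at ceiling.  The envelope-to-background
ratio is therefore higher than in physiological recordings; what the
simulations calibrate is the statistical pipeline, not the detector's
marginal-regime behavior.

What the generator does **not** emulate: K-complexes, REM phasic events,
traveling waves, realistic cross-channel noise correlation (background
noise is independent across channels; only the inserted events are
spatially coherent), occipital alpha, and the amplitude nonstationarity of
real sleep.  Passing tests therefore demonstrate correctness of the
computations and calibration of the statistics under a controlled signal
model — not detector performance on clinical recordings.

## Validation problem sizes

The test suite validates each stage against independent oracles: sample-by-
sample brute-force scans for both detectors, closed forms for rectified
sinusoids, inserted half-waves and Parseval sums, `signal::filtfilt` for
the zero-phase filters, `stats::t.test` / `cor.test` for the parametric
statistics, and igraph for cluster components.  The simulation experiments
use: family-wise error calibration on 1000 null datasets of 16+16 subjects
x 64 channels at 1024 permutations; effect-pattern recovery on 20 replicate
cohorts of 16+16 subjects, 8 channels, 30 minutes each with a 0.7 spindle
amplitude deficit (run without the average reference, for the low-channel
reason above); spindle-density recovery over 12 seeds at 4 channels.  These
sizes were chosen to give stable Monte-Carlo estimates while keeping the
whole suite runnable on a laptop; the calibration tolerances (±0.02 on the
5% error rate, ±10% on density recovery) reflect their Monte-Carlo error.

## Numerical choices and degenerate inputs

* Zero crossings are located by sign change with linear interpolation for
  sub-sample timing, which stabilizes slope denominators at 128 Hz.
* The 50-ms moving-average window is round(0.05 x fs) samples — 6 samples
  (46.9 ms) at 128 Hz; the corresponding Dirichlet-kernel attenuation of a
  1-Hz cosine derivative is 0.4%.
* EDF output uses a symmetric 16-bit digital range (±32767) so that 0 µV
  is representable exactly; round-trip error is bounded by one quantization
  step of the declared physical range.
* Zero pooled variance in a t-test yields t = 0 for equal means and signed
  infinity otherwise; constant input to the rank correlation yields NA.
* Channels with no retained epochs, empty stage selections, and empty
  clusters raise errors naming the empty intersection rather than
  propagating NaN.
* Epoch e (1-based) covers [30(e−1), 30e) seconds from recording start;
  hypnogram rows that end before lights-off are treated as wake.

## Known limitations

* EDF support covers plain continuous 16-bit EDF with one sampling rate
  across signals; EDF+ annotations and discontinuous files are out of
  scope.
* The spindle detector is the fixed-band 11–16 Hz method; individualized
  frequency-band adjustment is intentionally not implemented.
* Artifact handling is rejection only — no ocular regression, ICA, or
  bad-channel interpolation.
* The permutation test assumes exchangeable subjects under the null
  (two independent groups); paired or covariate-adjusted designs are not
  supported.
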