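# somnotype

Quantitative analysis of whole-night, multichannel sleep EEG, built around
two NREM graphoelements and their group statistics:

* **Sleep spindles** — 11–16 Hz thalamocortical bursts.  The detector
  rectifies the sigma-band signal and uses thresholds *relative to each
  channel's mean rectified amplitude* (lower 2x, upper 8x): a fluctuation
  exceeding the upper threshold is a spindle, bounded by the nearest
  crossings of the lower threshold, minimum duration 0.25 s.  Per channel
  the package reports density (events/min of analyzed NREM), mean duration,
  and **integrated spindle activity**,

  ISAs = Σ_events [ ∫ A(t) dt / duration ] / NREM minutes   (µV/min),

  an amplitude-weighted spindle burden that separates amplitude deficits
  from count deficits — reported for whole (12–16), slow (12–14) and fast
  (14–16 Hz) ranges.

* **Slow waves** — period-amplitude analysis of the 0.5–4 Hz signal:
  every negative half-wave between zero crossings (0.25–1.0 s, no amplitude
  criterion) yields NPAMP (negative peak amplitude), ADS/AUS (average
  down-/up-slopes) and MDS/MUS (maximal smoothed-derivative slopes), plus
  density.

Around these sit the supporting stages a sleep study needs: EDF input and
output, zero-phase Butterworth conditioning (0.1 Hz high-pass, resampling
to 128 Hz, 0.5–40 Hz band-pass, average reference), per-channel epoch
artifact rejection by relative band power in 0.8–4.48 and 20–30 Hz, Welch
spectra (five 6-s Hamming segments per 30-s epoch, 0.16-Hz resolution),
hypnogram-based sleep-architecture scoring with NREM-cycle detection, and
**supra-threshold cluster permutation tests** over electrode topographies:
per-channel unpaired t-maps are thresholded at the two-tailed critical t
(2.042 at df = 30), adjacency-connected clusters are scored by their t-mass,
and family-wise-corrected p-values come from the permutation distribution
of the maximal cluster statistic under group-label relabeling.

A synthetic-data module (`generate_hypnogram()`, `generate_recording()`,
`generate_cohort()`) produces staged multichannel recordings with 1/f
background, ground-truth spindle/slow-wave events, artifact epochs, and
two-group cohorts with configurable amplitude deficits and shared
densities, so detector accuracy, parameter recovery and the calibration of
the cluster statistics are all testable without any recordings.  It is
first-class, tested code — see the methods vignette
(`vignettes/sleep-eeg-methods.Rmd`) for the signal model and its limits.

Who this is for: sleep researchers and clinical neurophysiologists who
want a transparent, scriptable re-implementation of this spindle/slow-wave
workflow, and methodologists who want a calibrated testbed for
topographic permutation statistics.

## Worked example

Simulate one subject's night, condition it, and extract per-channel
spindle and slow-wave metrics:

```r
library(somnotype)

prof <- stage_profile(sleep_latency_min = 2, rem_latency_min = 15)
hyp  <- generate_hypnogram(30, seed = 1, profile = prof)
hyp
#> <hypnogram> 60 epochs of 30 s; lights 0-1800 s
#>   W:3 N1:2 N2:28 N3:26 REM:1

mon <- make_montage(8)
gr  <- generate_recording(hyp, mon, synth_config(n_channels = 8), seed = 1)
rec <- preprocess_recording(gr$recording, rereference = FALSE)

amask <- reject_artifacts(rec, hyp)                    # band-power outliers
mask  <- stage_mask(hyp, c("N2", "N3"), artifact_mask = amask)

ev <- detect_spindles(sigma_envelope(rec), mask)
spindle_metrics(ev, mask, labels = rec$labels, range = "whole")
#>  channel  n density duration   isas minutes
#>       E1 51    1.89     0.97 210.70      27
#>       E2 49    1.81     0.99 232.12      27
#>       E3 51    1.89     0.96 192.33      27
#>       ...
```

Each row is one electrode over its 27 artifact-free N2/N3 minutes: ~1.9
detected spindles per minute of about 1 s each, with ISAs highest near the
simulated centroparietal spindle maximum (E2).  Slow waves, analogously:

```r
sw <- detect_slow_waves(rec, mask)
slow_wave_metrics(sw, mask, labels = rec$labels)
#>  channel    n density npamp   ads   mds   aus   mus minutes
#>       E1 1391    51.5 -32.5 181.0 316.6 183.8 325.1      27
#>       E2 1416    52.4 -30.9 175.3 306.5 178.6 313.1      27
#>       ...
```

Density counts *every* negative 0.5–4 Hz half-wave (the period-amplitude
convention has no amplitude cutoff), so it is dominated by the delta
background; NPAMP and the four slopes are the amplitude-sensitive outcome
measures.  Architecture from the hypnogram:

```r
score_architecture(hyp)[, c("TST", "SE", "SL", "N2", "N3")]
#>   TST SE  SL   N2   N3
#>  28.5 95 1.5 49.1 45.6
```

For a two-group study, stack per-subject metrics into topographies and run
the cluster permutation test:

```r
topo_A <- topo_matrix(metrics_A, "isas")   # subjects x channels
topo_B <- topo_matrix(metrics_B, "isas")
adj    <- build_adjacency(mon)             # distance rule, 1.3x median NN
snpm_cluster_test(topo_A, topo_B, adj,
                  t_thresh = critical_t(0.05, 30), n_perm = 8192, seed = 1)
```

`run_study()` wires the whole chain together from a YAML config
(subjects, windows, parameters) to CSV reports; `make_fixture()` writes a
complete synthetic cohort (EDF + hypnograms + ground truth + config) to
disk for end-to-end runs.

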