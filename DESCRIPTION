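Package: somnotype
Title: Whole-Night High-Density Sleep EEG Analysis of Spindles and Slow Waves
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for whole-night high-density sleep EEG. Implements
    automated sleep spindle detection with amplitude thresholds relative to the
    mean of the rectified sigma-band signal and the integrated spindle activity
    (ISAs) statistic; period-amplitude analysis of slow waves (negative peak
    amplitude, average and maximal down-/up-slopes, density); Welch power
    spectral density with 0.16-Hz resolution; hypnogram-based sleep architecture
    scoring and NREM cycle detection; epoch-level artifact rejection by relative
    band power; and nonparametric supra-threshold cluster permutation tests over
    electrode topographies with family-wise error control. A synthetic-data
    module generates staged multichannel recordings with 1/f background,
    ground-truth spindle and slow-wave events, and two-group cohorts with
    configurable amplitude deficits, so detector accuracy, parameter recovery
    and statistical calibration can be tested end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    deldir,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
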