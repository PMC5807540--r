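# Automated spindle detection and the density / duration / ISAs metrics.
#
# The detector works on the amplitude of the band-passed (11-16 Hz) signal:
# per channel, thresholds are set relative to the mean amplitude over the
# analyzed NREM samples (lower = 2x mean, upper = 8x mean).  An amplitude
# fluctuation exceeding the upper threshold marks a spindle; its bounds are
# the nearest samples before and after the peak where amplitude drops below
# the lower threshold.  Events shorter than 0.25 s are discarded, and
# excursions sharing bounds are merged.

#' Detection parameters
#'
#' @param band detection band-pass, Hz.
#' @param lower,upper threshold factors applied to the channel mean amplitude.
#' @param min_dur minimum event duration, s.
#' @return Parameter list.
#' @export
spindle_params <- function(band = c(11, 16), lower = 2, upper = 8,
                           min_dur = 0.25) {
  if (!(0 < lower && lower < upper)) stopf("need 0 < lower < upper")
  if (band[1] >= band[2]) stopf("band lo must be < hi")
  list(band = band, lower = lower, upper = upper, min_dur = min_dur)
}

#' Sigma-band amplitude envelope
#'
#' Band-passes each channel (zero-phase) and rectifies it.  By default the
#' amplitude series is the upper envelope of the rectified signal (linear
#' interpolation through its local maxima), which tracks the instantaneous
#' burst amplitude; `method = "rectify"` returns the plain rectified signal,
#' whose mean over whole cycles of a sinusoid of amplitude a is 2a/pi.
#'
#' @param rec preprocessed [new_recording()].
#' @param band band edges, Hz (must lie below Nyquist).
#' @param method `"interp"` (upper envelope) or `"rectify"`.
#' @return Object of class `sigma_envelope`: list with `envelope` and
#'   `filtered` (channels x samples), `fs`, `labels`.
#' @export
sigma_envelope <- function(rec, band = c(11, 16),
                           method = c("interp", "rectify")) {
  method <- match.arg(method)
  if (band[2] >= rec$fs / 2) stopf("band extends beyond Nyquist")
  filt <- filtered_band(rec, band[1], band[2])
  rect <- abs(filt)
  env <- if (method == "interp") t(apply(rect, 1, upper_envelope)) else rect
  dimnames(env) <- dimnames(filt) <- dimnames(rect) <- list(rec$labels, NULL)
  structure(list(envelope = env, rectified = rect, filtered = filt,
                 fs = rec$fs, labels = rec$labels, band = band,
                 method = method),
            class = "sigma_envelope")
}

# sample-index mask from an epoch mask, per channel
sample_mask_for <- function(mask, labels, fs, n) {
  m <- mask_for(mask, labels)
  spe <- as.integer(round((attr(mask, "epoch_s") %||% 30) * fs))
  out <- matrix(FALSE, length(labels), n, dimnames = list(labels, NULL))
  n_ep <- min(ncol(m), n %/% spe)
  out[, seq_len(n_ep * spe)] <- m[, rep(seq_len(n_ep), each = spe)]
  out
}

#' Detect sleep spindles
#'
#' @param env a [sigma_envelope()].  Thresholds are factors of the channel's
#'   mean *rectified* amplitude over the masked samples (the mean of the
#'   band-passed, rectified signal); the threshold scan runs on the amplitude
#'   envelope.
#' @param mask `epoch_mask` of the analyzed NREM epochs; channel mean
#'   amplitudes (hence thresholds) are computed over these samples only.
#' @param params [spindle_params()].
#' @return Data frame of events: `channel, start_s, end_s, duration,
#'   peak_amp, mean_amp, freq` (mean frequency from zero crossings of the
#'   band-passed signal within the event).  Attribute `mean_amp` holds the
#'   per-channel mean amplitudes.
#' @export
detect_spindles <- function(env, mask, params = spindle_params()) {
  stopifnot(inherits(env, "sigma_envelope"))
  fs <- env$fs
  n <- ncol(env$envelope)
  smask <- sample_mask_for(mask, env$labels, fs, n)
  if (!any(smask)) stopf("empty mask: no samples to analyze")
  out <- vector("list", length(env$labels))
  means <- setNames(numeric(length(env$labels)), env$labels)
  rect <- env$rectified %||% abs(env$filtered)
  for (ch in seq_along(env$labels)) {
    e <- env$envelope[ch, ]
    ok <- smask[ch, ]
    if (!any(ok)) next
    mu <- mean(rect[ch, ok])
    means[ch] <- mu
    thr_lo <- params$lower * mu
    thr_up <- params$upper * mu
    below <- which(e < thr_lo | !ok)
    supra <- which(e > thr_up & ok)
    if (!length(supra)) next
    # bounds: nearest below-lower samples around each supra-upper excursion
    ins <- findInterval(supra, below)
    start <- ifelse(ins >= 1L, below[pmax(ins, 1L)], 0L)
    idx_end <- ins + 1L
    end <- ifelse(idx_end <= length(below), below[pmin(idx_end, length(below))],
                  n + 1L)
    key <- !duplicated(paste(start, end))
    start <- start[key]; end <- end[key]
    dur <- (end - start) / fs
    keep <- dur >= params$min_dur
    start <- start[keep]; end <- end[keep]; dur <- dur[keep]
    if (!length(start)) next
    s0 <- pmax(start, 1L); s1 <- pmin(end, n)
    f <- env$filtered[ch, ]
    feats <- vapply(seq_along(s0), function(k) {
      seg <- s0[k]:s1[k]
      es <- e[seg]
      zc <- which(diff(sign(f[seg])) != 0)
      mf <- if (length(zc) >= 2L)
        (length(zc) - 1) / (2 * (zc[length(zc)] - zc[1]) / fs) else NA_real_
      c(max(es), mean(es), mf)
    }, numeric(3))
    out[[ch]] <- data.frame(channel = env$labels[ch],
                            start_s = (s0 - 1) / fs, end_s = (s1 - 1) / fs,
                            duration = dur, peak_amp = feats[1, ],
                            mean_amp = feats[2, ], freq = feats[3, ])
  }
  ev <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(ev))
    ev <- data.frame(channel = character(), start_s = numeric(),
                     end_s = numeric(), duration = numeric(),
                     peak_amp = numeric(), mean_amp = numeric(),
                     freq = numeric())
  rownames(ev) <- NULL
  attr(ev, "mean_amp") <- means
  ev
}

#' Filter spindle events by mean-frequency range
#'
#' Ranges follow the half-open convention slow = \[12, 14), fast = \[14, 16\]
#' (boundary 14 Hz assigned to fast), whole = their union.
#'
#' @param events [detect_spindles()] output.
#' @param range `"whole"`, `"slow"`, `"fast"`, or a numeric `c(lo, hi)`.
#' @return Subset of `events`.
#' @export
spindle_range <- function(events, range = "whole") {
  if (is.character(range)) {
    keep <- switch(range,
      whole = events$freq >= 12 & events$freq <= 16,
      slow = events$freq >= 12 & events$freq < 14,
      fast = events$freq >= 14 & events$freq <= 16,
      stopf("unknown range '%s'", range))
  } else {
    keep <- events$freq >= range[1] & events$freq < range[2]
  }
  events[which(keep), , drop = FALSE]
}

#' Per-channel spindle metrics
#'
#' Density = events per minute of analyzed NREM; mean duration; ISAs =
#' sum over events of the time-integral of the amplitude envelope divided by
#' event duration (i.e. the event mean amplitude), divided by analyzed NREM
#' minutes (µV/min).
#'
#' @param events [detect_spindles()] output (optionally range-filtered).
#' @param mask `epoch_mask` defining the analyzed time per channel.
#' @param labels channel labels to report (defaults to mask rows).
#' @param range optional range passed to [spindle_range()].
#' @return Data frame `channel, n, density, duration, isas, minutes`.
#' @export
spindle_metrics <- function(events, mask, labels = NULL, range = NULL) {
  labels <- labels %||% (if (nrow(mask) == 1L && rownames(mask)[1] == ".all")
    unique(events$channel) else rownames(mask))
  if (!length(labels)) stopf("no channels to report")
  minutes <- mask_minutes(mask, labels)
  if (any(minutes <= 0)) stopf("zero retained time on channel %s",
                               labels[which(minutes <= 0)[1]])
  if (!is.null(range)) events <- spindle_range(events, range)
  res <- lapply(labels, function(ch) {
    ev <- events[events$channel == ch, , drop = FALSE]
    data.frame(channel = ch, n = nrow(ev),
               density = nrow(ev) / minutes[[ch]],
               duration = if (nrow(ev)) mean(ev$duration) else NA_real_,
               isas = if (nrow(ev)) sum(ev$mean_amp) / minutes[[ch]] else 0,
               minutes = minutes[[ch]])
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
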