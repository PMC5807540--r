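# Period-amplitude slow-wave analysis: negative half-waves between
# consecutive zero crossings of the 0.5-4 Hz filtered signal, regardless of
# amplitude (no microvolt criterion by default), with amplitude and slope
# parameters per half-wave.

#' Detect slow waves (negative half-wave analysis)
#'
#' The signal is zero-phase band-pass filtered, zero crossings are located
#' with linear interpolation, and every negative half-wave whose duration
#' (up-crossing minus down-crossing) lies within `dur_range` becomes an
#' event.  Parameters per event: NPAMP, the most negative sample between the
#' two crossings; ADS / AUS, `|NPAMP|` divided by the time from the
#' down-crossing to the peak / from the peak to the up-crossing; MDS / MUS,
#' the maximum absolute first-difference derivative after a 50-ms centered
#' moving average, over the falling / rising segment.  Half-waves straddling
#' mask boundaries are discarded.  An optional amplitude criterion
#' (`min_npamp`) can restrict events to `|NPAMP| >=` a threshold.
#'
#' @param rec preprocessed [new_recording()].
#' @param mask `epoch_mask` of the analyzed epochs.
#' @param band detection band-pass, Hz; `NULL` skips the internal filter
#'   (signal treated as already band-limited — the filter's two-pass response
#'   attenuates isolated pulses, so measurement-definition checks against
#'   closed forms use this path).
#' @param dur_range admissible half-wave duration, s.
#' @param min_npamp optional amplitude criterion, µV (default none).
#' @param ma_s moving-average window for the maximal slopes, s.
#' @return Data frame: `channel, start_s, end_s, t_peak, duration, npamp,
#'   ads, aus, mds, mus` (slopes in µV/s, positive magnitudes; npamp <= 0).
#' @export
detect_slow_waves <- function(rec, mask, band = c(0.5, 4),
                              dur_range = c(0.25, 1.0), min_npamp = NULL,
                              ma_s = 0.05) {
  fs <- rec$fs
  filt <- if (is.null(band)) rec$data else filtered_band(rec, band[1], band[2])
  n <- ncol(filt)
  smask <- sample_mask_for(mask, rec$labels, fs, n)
  if (!any(smask)) stopf("empty mask: no samples to analyze")
  w <- max(1L, as.integer(round(ma_s * fs)))
  out <- vector("list", length(rec$labels))
  for (ch in seq_along(rec$labels)) {
    x <- filt[ch, ]
    ok <- smask[ch, ]
    if (!any(ok)) next
    s <- sign(x)
    dn <- which(s[-n] >= 0 & s[-1] < 0)     # down-going crossing in (i, i+1)
    up <- which(s[-n] < 0 & s[-1] >= 0)     # up-going crossing in (i, i+1)
    if (!length(dn) || !length(up)) next
    # pair each down-crossing with the first later up-crossing
    ui <- findInterval(dn, up) + 1L
    valid <- ui <= length(up)
    d <- dn[valid]; u <- up[ui[valid]]
    if (!length(d)) next
    tx <- function(i) (i - 1 + x[i] / (x[i] - x[i + 1])) / fs
    t_d <- tx(d); t_u <- tx(u)
    dur <- t_u - t_d
    keep <- dur >= dur_range[1] & dur <= dur_range[2]
    # mask: every sample in (d, u] must be retained
    badcum <- cumsum(!ok)
    keep <- keep & (badcum[u] - badcum[d]) == 0
    d <- d[keep]; u <- u[keep]; t_d <- t_d[keep]; t_u <- t_u[keep]
    dur <- dur[keep]
    if (!length(d)) next
    deriv <- moving_average(c(diff(x), 0) * fs, w)
    feats <- vapply(seq_along(d), function(k) {
      seg <- (d[k] + 1L):u[k]
      j <- which.min(x[seg])
      i_pk <- seg[j]
      c(i_pk, x[i_pk],
        max(abs(deriv[d[k]:i_pk])), max(abs(deriv[i_pk:u[k]])))
    }, numeric(4))
    i_pk <- feats[1, ]; npamp <- feats[2, ]
    t_p <- (i_pk - 1) / fs
    sane <- t_d < t_p & t_p < t_u
    if (!is.null(min_npamp)) sane <- sane & abs(npamp) >= min_npamp
    if (!any(sane)) next
    out[[ch]] <- data.frame(
      channel = rec$labels[ch], start_s = t_d[sane], end_s = t_u[sane],
      t_peak = t_p[sane], duration = dur[sane], npamp = npamp[sane],
      ads = abs(npamp[sane]) / (t_p[sane] - t_d[sane]),
      aus = abs(npamp[sane]) / (t_u[sane] - t_p[sane]),
      mds = feats[3, sane], mus = feats[4, sane])
  }
  ev <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(ev))
    ev <- data.frame(channel = character(), start_s = numeric(),
                     end_s = numeric(), t_peak = numeric(),
                     duration = numeric(), npamp = numeric(), ads = numeric(),
                     aus = numeric(), mds = numeric(), mus = numeric())
  rownames(ev) <- NULL
  ev
}

#' Per-channel slow-wave metrics
#'
#' Density (waves per analyzed minute) and means of NPAMP, ADS, MDS, AUS,
#' MUS.  Channels without events report density 0 and `NA` means.
#'
#' @param events [detect_slow_waves()] output.
#' @param mask `epoch_mask` defining analyzed time.
#' @param labels channels to report.
#' @return Data frame `channel, n, density, npamp, ads, mds, aus, mus,
#'   minutes`.
#' @export
slow_wave_metrics <- function(events, mask, labels = NULL) {
  labels <- labels %||% (if (nrow(mask) == 1L && rownames(mask)[1] == ".all")
    unique(events$channel) else rownames(mask))
  if (!length(labels)) stopf("no channels to report")
  minutes <- mask_minutes(mask, labels)
  if (any(minutes <= 0)) stopf("zero retained time on channel %s",
                               labels[which(minutes <= 0)[1]])
  res <- lapply(labels, function(ch) {
    ev <- events[events$channel == ch, , drop = FALSE]
    m <- function(col) if (nrow(ev)) mean(ev[[col]]) else NA_real_
    data.frame(channel = ch, n = nrow(ev), density = nrow(ev) / minutes[[ch]],
               npamp = m("npamp"), ads = m("ads"), mds = m("mds"),
               aus = m("aus"), mus = m("mus"), minutes = minutes[[ch]])
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
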