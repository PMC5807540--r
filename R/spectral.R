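# Welch spectral estimation with the pipeline's fixed segmentation:
# each retained 30-s epoch is split into five non-overlapping 6-s
# Hamming-windowed segments (0.1667-Hz bin resolution at 128 Hz).

#' Welch power spectral density
#'
#' One-sided density in µV²/Hz, normalized so that the integral over
#' frequency recovers the signal variance (Parseval).  Periodograms are
#' averaged within and across the retained 30-s epochs of each channel.
#'
#' @param rec preprocessed [new_recording()].
#' @param mask `epoch_mask` from [stage_mask()] / [reject_artifacts()].
#' @param seg_s segment length in seconds (5 segments per epoch at 6 s).
#' @return Object of class `psd`: list with `freq` (Hz), `power`
#'   (channels x bins), `n_epochs` per channel, `labels`, `df`.
#' @export
welch_psd <- function(rec, mask, seg_s = 6) {
  fs <- rec$fs
  spe <- as.integer(round(30 * fs))
  n_ep <- n_samples(rec) %/% spe
  m <- mask_for(mask, rec$labels)[, seq_len(min(n_ep, ncol(mask))), drop = FALSE]
  if (!any(m)) stopf("no retained epochs to average")
  nseg <- as.integer(round(seg_s * fs))
  k <- spe %/% nseg
  w <- signal::hamming(nseg)
  U <- sum(w^2)
  nfr <- nseg %/% 2 + 1L
  freq <- (0:(nfr - 1)) * fs / nseg
  power <- matrix(NA_real_, n_channels(rec), nfr,
                  dimnames = list(rec$labels, NULL))
  n_used <- integer(n_channels(rec))
  for (ch in seq_len(n_channels(rec))) {
    eps <- which(m[ch, ])
    if (!length(eps)) next
    idx <- rep((eps - 1L) * spe, each = spe) + seq_len(spe)
    S <- matrix(rec$data[ch, idx], nrow = spe)[seq_len(k * nseg), , drop = FALSE]
    S <- matrix(S, nrow = nseg)
    P <- Mod(stats::mvfft(S * w))^2 / (fs * U)
    P <- P[seq_len(nfr), , drop = FALSE]
    P[2:(nfr - 1), ] <- 2 * P[2:(nfr - 1), ]
    power[ch, ] <- rowMeans(P)
    n_used[ch] <- length(eps)
  }
  if (all(n_used == 0L)) stopf("no retained epochs to average")
  structure(list(freq = freq, power = power, n_epochs = n_used,
                 labels = rec$labels, df = fs / nseg),
            class = "psd")
}

#' @export
print.psd <- function(x, ...) {
  cat(sprintf("<psd> %d channels, %d bins, df = %.4f Hz\n",
              nrow(x$power), length(x$freq), x$df))
  invisible(x)
}

#' Integrated band power
#'
#' Sum of `power x df` over bins whose centers lie in `[lo, hi)`.
#'
#' @param psd a [welch_psd()] result.
#' @param band numeric `c(lo, hi)` in Hz.
#' @return Named per-channel numeric vector, µV².
#' @export
band_power <- function(psd, band) {
  if (band[2] <= band[1]) stopf("empty band")
  sel <- which(psd$freq >= band[1] & psd$freq < band[2])
  if (!length(sel)) stopf("empty band: no bins in [%g, %g)", band[1], band[2])
  setNames(rowSums(psd$power[, sel, drop = FALSE]) * psd$df, psd$labels)
}

#' Write a PSD to CSV (`channel,freq_hz,power`)
#' @param psd a [welch_psd()] result.
#' @param path output path.
#' @export
write_psd <- function(psd, path) {
  df <- data.frame(channel = rep(psd$labels, each = length(psd$freq)),
                   freq_hz = rep(psd$freq, length(psd$labels)),
                   power = as.vector(t(psd$power)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
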