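# Signal conditioning: high-pass, resampling, band-pass, average reference,
# and epoch-level artifact rejection by relative band power.

#' Precondition a raw recording
#'
#' Applies, in order: zero-phase high-pass at `hp` Hz, resampling to
#' `target_fs` Hz (polyphase rational resampler), zero-phase band-pass
#' `bp`, and re-referencing to the instantaneous average of all channels.
#' All filters are 4th-order Butterworth designs applied with zero phase.
#'
#' @param rec an [new_recording()] with `fs >= target_fs`.
#' @param hp high-pass cutoff, Hz.
#' @param target_fs output sampling rate, Hz.
#' @param bp band-pass edges, Hz.
#' @param rereference apply the average reference (default TRUE).
#' @return A preprocessed [new_recording()] at `target_fs`.
#' @export
preprocess_recording <- function(rec, hp = 0.1, target_fs = 128,
                                 bp = c(0.5, 40), rereference = TRUE) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (rec$fs < target_fs)
    stopf("unsupported input: fs %g Hz is below the target %g Hz",
          rec$fs, target_fs)
  if (rec$fs == target_fs) {
    X <- rec$data
  } else {
    X <- zerophase_filter(rec$data, rec$fs, lo = hp)
    frac <- ratio_approx(target_fs / rec$fs)
    X <- t(apply(X, 1, function(x) signal::resample(x, frac[1], frac[2])))
  }
  # band-pass (and, absent resampling, the fused high-pass) in one pass;
  # the raw spectrum and applied gain are cached so later band filters of
  # the result can reuse them (see filtered_band)
  n <- ncol(X)
  nchn <- nrow(X)
  G <- band_gain(n, target_fs, lo = bp[1], hi = bp[2])
  if (rec$fs == target_fs) G <- G * band_gain(n, target_fs, lo = hp)
  Ft <- stats::mvfft(pack_channels(X))
  X <- unpack_channels(stats::mvfft(Ft * G, inverse = TRUE) / n, nchn)
  if (rereference) X <- sweep(X, 2, colMeans(X))
  rownames(X) <- rec$labels
  out <- new_recording(X, target_fs, labels = rec$labels,
                       reference = if (rereference) "average" else rec$reference,
                       start_time = rec$start_time)
  attr(out, "fspec") <- list(F = Ft, gain = G, rereference = rereference)
  out
}

# Band-pass a preprocessed recording, reusing its cached raw spectrum when
# available (average referencing commutes with linear filtering).
filtered_band <- function(rec, lo, hi, order = 4) {
  n <- ncol(rec$data)
  cache <- attr(rec, "fspec")
  if (!is.null(cache) && nrow(cache$F) == n) {
    G2 <- band_gain(n, rec$fs, lo, hi, order)
    Y <- unpack_channels(stats::mvfft(cache$F * (cache$gain * G2),
                                      inverse = TRUE) / n, nrow(rec$data))
    if (isTRUE(cache$rereference)) Y <- sweep(Y, 2, colMeans(Y))
    dimnames(Y) <- dimnames(rec$data)
    return(Y)
  }
  zerophase_filter(rec$data, rec$fs, lo = lo, hi = hi, order = order)
}

# small rational approximation p/q of a ratio in (0, 1]
ratio_approx <- function(r, max_den = 1000) {
  best <- c(1L, 1L); err <- Inf
  for (q in 1:max_den) {
    p <- round(r * q)
    if (p < 1) next
    e <- abs(p / q - r)
    if (e < err - 1e-15) { err <- e; best <- c(p, q) }
    if (err < 1e-12) break
  }
  as.integer(best)
}

#' Reject artifact epochs by relative band power
#'
#' Per channel, 30-s epochs of the analyzed NREM stages whose band power
#' exceeds `factor x` that channel's mean NREM power in either the low
#' (0.8-4.48 Hz) or high (20-30 Hz) band are marked rejected.  Power is the
#' Welch estimate of [welch_psd()] computed epoch by epoch.  The mask is
#' per-channel: an artifact on one channel does not discard the epoch
#' elsewhere.
#'
#' @param rec preprocessed [new_recording()] (fs 128).
#' @param hyp matching [hypnogram()].
#' @param low_band,high_band frequency bands, Hz.
#' @param factor_low,factor_high rejection multipliers of the channel mean.
#' @param stages stages over which means are formed and rejection applies.
#' @return Logical channels x epochs matrix (`TRUE` = retained), class
#'   `epoch_mask`; epochs outside `stages` are retained by convention.
#' @export
reject_artifacts <- function(rec, hyp, low_band = c(0.8, 4.48),
                             high_band = c(20, 30),
                             factor_low = 4, factor_high = 4,
                             stages = c("N2", "N3")) {
  spe <- as.integer(round(30 * rec$fs))
  n_ep <- min(n_epochs(hyp), n_samples(rec) %/% spe)
  nrem <- which(hyp$stages[seq_len(n_ep)] %in% stages)
  if (length(nrem) < 2L) stopf("need at least 2 NREM epochs for artifact rejection")
  pow <- epoch_band_powers(rec, nrem, list(low_band, high_band))
  mask <- matrix(TRUE, n_channels(rec), n_ep,
                 dimnames = list(rec$labels, NULL))
  for (b in 1:2) {
    fac <- if (b == 1) factor_low else factor_high
    mu <- rowMeans(pow[[b]])
    mask[, nrem][pow[[b]] > fac * mu] <- FALSE
  }
  structure(mask, class = c("epoch_mask", "matrix", "array"), epoch_s = 30)
}

# per-channel Welch band powers over the given epochs
# (list of channels x length(epochs) matrices)
epoch_band_powers <- function(rec, epochs, bands, seg_s = 6) {
  fs <- rec$fs
  spe <- as.integer(round(30 * fs))
  nseg <- as.integer(round(seg_s * fs))
  k <- spe %/% nseg
  w <- signal::hamming(nseg)
  U <- sum(w^2)
  freq <- (0:(nseg %/% 2)) * fs / nseg
  nfr <- length(freq)
  sel <- lapply(bands, function(b) which(freq >= b[1] & freq < b[2]))
  df <- fs / nseg
  n_ep <- length(epochs)
  idx <- rep((epochs - 1L) * spe, each = spe) + seq_len(spe)
  out <- lapply(bands, function(b) matrix(0, n_channels(rec), n_ep))
  for (ch in seq_len(n_channels(rec))) {
    S <- matrix(rec$data[ch, idx], nrow = spe)[seq_len(k * nseg), , drop = FALSE]
    S <- matrix(S, nrow = nseg)          # nseg x (k * n_ep) segments
    P <- Mod(stats::mvfft(S * w))^2 / (fs * U)
    P <- P[seq_len(nfr), , drop = FALSE]
    P[2:(nfr - 1), ] <- 2 * P[2:(nfr - 1), ]
    for (b in seq_along(bands)) {
      bp <- colSums(P[sel[[b]], , drop = FALSE]) * df
      out[[b]][ch, ] <- colMeans(matrix(bp, nrow = k))
    }
  }
  out
}
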