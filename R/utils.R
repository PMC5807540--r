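# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Squared magnitude response of a digital Butterworth filter
#'
#' Evaluated on the n-point DFT frequency grid.  Multiplying a spectrum by
#' this response is the transfer function of forward-backward (zero-phase)
#' filtering with the same design.
#'
#' @param n number of DFT points.
#' @param fs sampling rate, Hz.
#' @param w cutoff (scalar for high/low, length-2 for pass), Hz.
#' @param order filter order (of one pass).
#' @param type "high", "low" or "pass".
#' @noRd
butter_gain2 <- function(n, fs, w, order = 4, type) {
  ba <- signal::butter(order, w / (fs / 2), type = type)
  zi <- exp(-2i * pi * (0:(n - 1)) / n)
  hb <- rep(ba$b[length(ba$b)] + 0i, n)
  for (k in rev(seq_len(length(ba$b) - 1))) hb <- hb * zi + ba$b[k]
  ha <- rep(ba$a[length(ba$a)] + 0i, n)
  for (k in rev(seq_len(length(ba$a) - 1))) ha <- ha * zi + ba$a[k]
  Mod(hb / ha)^2
}

.gain_cache <- new.env(parent = emptyenv())

band_gain <- function(n, fs, lo = NULL, hi = NULL, order = 4) {
  key <- paste(n, fs, lo %||% "", hi %||% "", order, sep = "|")
  hit <- get0(key, envir = .gain_cache)
  if (!is.null(hit)) return(hit)
  g <- if (!is.null(lo) && !is.null(hi)) {
    if (hi >= fs / 2) stopf("band edge %g Hz is at or above Nyquist (%g Hz)", hi, fs / 2)
    butter_gain2(n, fs, c(lo, hi), order, "pass")
  } else if (!is.null(lo)) {
    butter_gain2(n, fs, lo, order, "high")
  } else if (!is.null(hi)) {
    butter_gain2(n, fs, hi, order, "low")
  } else rep(1, n)
  assign(key, g, envir = .gain_cache)
  g
}

# Pack pairs of real channels into complex columns (samples x npair): for
# real filter gains, Re/Im of the inverse transform recover the two
# channels, halving FFT work.
pack_channels <- function(X) {
  nchn <- nrow(X); n <- ncol(X)
  npair <- (nchn + 1L) %/% 2L
  Z <- matrix(0 + 0i, n, npair)
  for (p in seq_len(npair)) {
    i1 <- 2L * p - 1L
    Z[, p] <- if (2L * p <= nchn) X[i1, ] + 1i * X[i1 + 1L, ] else X[i1, ] + 0i
  }
  Z
}

unpack_channels <- function(Y, nchn) {
  n <- nrow(Y)
  out <- matrix(0, nchn, n)
  for (p in seq_len(ncol(Y))) {
    i1 <- 2L * p - 1L
    out[i1, ] <- Re(Y[, p])
    if (2L * p <= nchn) out[i1 + 1L, ] <- Im(Y[, p])
  }
  out
}

# Apply one or several real zero-phase gains to a channels x samples matrix,
# sharing a single (packed) forward FFT across bands.
apply_gains <- function(X, gains) {
  n <- ncol(X)
  Fz <- stats::mvfft(pack_channels(X))
  lapply(gains, function(G) {
    Y <- unpack_channels(stats::mvfft(Fz * G, inverse = TRUE) / n, nrow(X))
    dimnames(Y) <- dimnames(X)
    Y
  })
}

#' Zero-phase band filter of a channels x samples matrix
#' @noRd
zerophase_filter <- function(X, fs, lo = NULL, hi = NULL, order = 4) {
  apply_gains(X, list(band_gain(ncol(X), fs, lo, hi, order)))[[1]]
}

# Upper envelope of a non-negative series: linear interpolation through its
# local maxima (first/last samples kept as anchors).
upper_envelope <- function(r) {
  n <- length(r)
  if (n < 3L) return(r)
  mid <- r[2:(n - 1)]
  peak <- which(mid >= r[1:(n - 2)] & mid > r[3:n]) + 1L
  idx <- unique(c(1L, peak, n))
  if (length(idx) < 2L) return(r)
  stats::approx(idx, r[idx], xout = seq_len(n))$y
}

# Centered moving average; edges shrink to the available window.
moving_average <- function(x, w) {
  if (w <= 1L) return(x)
  y <- stats::filter(x, rep(1 / w, w), sides = 2)
  y <- as.numeric(y)
  # fill edge NAs with partial-window means
  half <- floor(w / 2)
  n <- length(x)
  for (i in which(is.na(y))) {
    lo <- max(1L, i - half); hi <- min(n, i + (w - 1L - half))
    y[i] <- mean(x[lo:hi])
  }
  y
}

# Deterministic child seeds derived from a master seed (kept below 2^31).
derive_seeds <- function(seed, n) {
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}
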