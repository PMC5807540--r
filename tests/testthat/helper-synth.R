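# Shared fixtures and independent oracles, built in code at test time.

# epoch mask of n_ep fully retained 30-s epochs (broadcast to all channels)
full_mask <- function(n_ep) {
  structure(matrix(TRUE, 1, n_ep, dimnames = list(".all", NULL)),
            class = c("epoch_mask", "matrix", "array"), epoch_s = 30)
}

# a recording of near-quiet Gaussian noise
quiet_recording <- function(nch = 1, dur_s = 120, fs = 128, sd = 0.01,
                            seed = 1) {
  set.seed(seed)
  new_recording(matrix(rnorm(nch * dur_s * fs, 0, sd), nch, dur_s * fs), fs)
}

# build a sigma_envelope object directly from an amplitude series (the
# rectified series equals the envelope, so thresholds are factors of its
# mean); `filtered` carries a sinusoid only so event frequency is defined
fake_envelope <- function(e, fs = 128, freq = 13) {
  n <- length(e)
  f <- sin(2 * pi * freq * (0:(n - 1)) / fs)
  structure(list(envelope = matrix(e, 1, n, dimnames = list("E1", NULL)),
                 rectified = matrix(e, 1, n, dimnames = list("E1", NULL)),
                 filtered = matrix(f, 1, n, dimnames = list("E1", NULL)),
                 fs = fs, labels = "E1", band = c(11, 16), method = "interp"),
            class = "sigma_envelope")
}

# brute-force spindle scan: sample-by-sample implementation of the
# threshold rules (upper excursion -> expand to below-lower bounds,
# merge shared bounds, minimum duration)
brute_spindle_scan <- function(e, thr_lo, thr_up, fs, min_dur = 0.25) {
  n <- length(e)
  events <- list()
  for (i in seq_len(n)) {
    if (e[i] <= thr_up) next
    s <- 0L
    if (i > 1L) for (j in (i - 1L):1L) if (e[j] < thr_lo) { s <- j; break }
    en <- n + 1L
    if (i < n) for (j in (i + 1L):n) if (e[j] < thr_lo) { en <- j; break }
    events[[length(events) + 1L]] <- c(s, en)
  }
  if (!length(events)) return(matrix(numeric(), 0, 2))
  ev <- unique(do.call(rbind, events))
  ev[(ev[, 2] - ev[, 1]) / fs >= min_dur, , drop = FALSE]
}

# brute-force negative half-wave scan on a band-limited signal
brute_halfwave_scan <- function(x, fs, dur_range = c(0.25, 1)) {
  n <- length(x)
  out <- list()
  i <- 1L
  while (i < n) {
    if (x[i] >= 0 && x[i + 1] < 0) {
      j <- i + 1L
      while (j < n && x[j + 1] < 0) j <- j + 1L
      if (j < n) {
        td <- (i - 1 + x[i] / (x[i] - x[i + 1])) / fs
        tu <- (j - 1 + x[j] / (x[j] - x[j + 1])) / fs
        dur <- tu - td
        if (dur >= dur_range[1] && dur <= dur_range[2]) {
          seg <- (i + 1L):j
          out[[length(out) + 1L]] <- c(td, tu, min(x[seg]))
        }
      }
      i <- j
    } else i <- i + 1L
  }
  if (!length(out)) return(matrix(numeric(), 0, 3))
  do.call(rbind, out)
}

# insert a Hann-enveloped sinusoid burst into a recording (in place)
insert_burst <- function(rec, channel, t0, dur, freq, amp) {
  fs <- rec$fs
  i0 <- floor(t0 * fs) + 1L
  i1 <- min(floor((t0 + dur) * fs), ncol(rec$data))
  tt <- ((i0:i1) - 1) / fs - t0
  rec$data[channel, i0:i1] <- rec$data[channel, i0:i1] +
    amp * 0.5 * (1 - cos(2 * pi * tt / dur)) * sin(2 * pi * freq * tt)
  rec
}

# insert an isolated negative half-sine
insert_halfwave <- function(rec, channel, t0, dur, npamp_abs) {
  fs <- rec$fs
  i0 <- floor(t0 * fs) + 1L
  i1 <- min(floor((t0 + dur) * fs), ncol(rec$data))
  tt <- ((i0:i1) - 1) / fs - t0
  rec$data[channel, i0:i1] <- rec$data[channel, i0:i1] -
    npamp_abs * sin(pi * tt / dur)
  rec
}

# run the per-subject cohort analysis used by the group simulations
cohort_subject_metrics <- function(man, i, effect, mon, cfg, prof,
                                   duration_min = 30) {
  sub <- cohort_subject(man, i, effect, duration_min, mon, cfg, prof)
  rec <- preprocess_recording(sub$recording, rereference = FALSE)
  amask <- reject_artifacts(rec, sub$hypnogram)
  mask <- stage_mask(sub$hypnogram, c("N2", "N3"), artifact_mask = amask)
  ev <- detect_spindles(sigma_envelope(rec), mask)
  spindle_metrics(ev, mask, labels = rec$labels, range = "whole")
}
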