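#' Multichannel EEG recording
#'
#' Container for a multichannel time series in microvolts.  Data are stored
#' channels x samples with a single sampling rate for all channels.
#'
#' @param data numeric matrix, channels x samples, in microvolts.
#' @param fs sampling rate in Hz (> 0).
#' @param labels character vector of unique channel labels; defaults to the
#'   rownames of `data` or `E1..En`.
#' @param reference `"as-recorded"` or `"average"`.
#' @param start_time recording start, seconds (offset convention: time t of
#'   sample k is `start_time + (k-1)/fs`).
#'
#' @return An object of class `eeg_recording` with fields `data`, `fs`,
#'   `labels`, `reference`, `start_time`.
#' @export
new_recording <- function(data, fs, labels = NULL,
                          reference = c("as-recorded", "average"),
                          start_time = 0) {
  if (!is.matrix(data) || !is.numeric(data))
    stopf("data must be a numeric channels x samples matrix")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stopf("fs must be a single positive number")
  reference <- match.arg(reference)
  labels <- labels %||% rownames(data) %||% paste0("E", seq_len(nrow(data)))
  if (length(labels) != nrow(data)) stopf("labels length != number of channels")
  if (anyDuplicated(labels)) stopf("channel labels must be unique")
  rownames(data) <- labels
  structure(
    list(data = data, fs = fs, labels = labels,
         reference = reference, start_time = start_time),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), reference: %s\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs, x$reference))
  invisible(x)
}

n_channels <- function(rec) nrow(rec$data)
n_samples <- function(rec) ncol(rec$data)
rec_duration <- function(rec) ncol(rec$data) / rec$fs
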