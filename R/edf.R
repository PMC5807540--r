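# Minimal EDF (European Data Format, 16-bit) reader and writer.
# Covers plain continuous EDF with identical sampling rate across signals,
# physical units in microvolts.  EDF+ annotations and discontinuous files are
# out of scope.

pad_ascii <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) stopf("EDF header field too long: '%s' (max %d)", x, width)
  formatC(x, width = -width)
}

# format a number into <= 8 ascii chars, re-parseable
fmt_edf_num <- function(x) {
  for (d in 7:1) {
    s <- formatC(x, digits = d, format = "g", width = 1)
    if (nchar(s) <= 8) return(s)
  }
  stopf("cannot format %g into 8 chars", x)
}

#' Write a recording to an EDF file
#'
#' Stores the recording as 16-bit EDF with a symmetric physical range covering
#' the data.  The quantization step is `(phys_max - phys_min) / 65535`.
#'
#' @param rec an [new_recording()] object with finite data.
#' @param path output file path.
#' @param physical_max optional physical range bound in microvolts; defaults to
#'   the maximum absolute sample value (at least 1).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, physical_max = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  X <- rec$data
  if (!all(is.finite(X))) stopf("recording contains non-finite samples")
  ns <- ncol(X); nch <- nrow(X); fs <- rec$fs
  if (!is.null(physical_max) && max(abs(X)) > physical_max)
    stopf("physical range does not cover the data")

  # one 1-s record per second when possible, else a single record
  if (abs(fs - round(fs)) < 1e-9 && ns >= fs && ns %% round(fs) == 0) {
    spr <- as.integer(round(fs)); n_rec <- ns %/% spr; rec_dur <- "1"
  } else {
    spr <- ns; n_rec <- 1L; rec_dur <- fmt_edf_num(ns / fs)
  }

  pm <- physical_max %||% max(abs(X), 1)
  pm_s <- fmt_edf_num(pm)
  pm <- as.numeric(pm_s)            # use the value as written
  pmin <- -pm; pmax <- pm
  dmin <- -32767L; dmax <- 32767L      # symmetric so 0 uV is exact

  dig <- round((X - pmin) / (pmax - pmin) * 65534 - 32767)
  dig <- pmin(pmax(dig, dmin), dmax)
  storage.mode(dig) <- "integer"

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_ascii("0", 8), pad_ascii("X", 80), pad_ascii("somnotype", 80),
    pad_ascii("01.01.00", 8), pad_ascii("00.00.00", 8),
    pad_ascii(256 * (nch + 1), 8), pad_ascii("", 44),
    pad_ascii(n_rec, 8), pad_ascii(rec_dur, 8), pad_ascii(nch, 4)
  )
  sig <- paste0(
    paste(vapply(rec$labels, pad_ascii, "", width = 16), collapse = ""),
    paste(rep(pad_ascii("", 80), nch), collapse = ""),
    paste(rep(pad_ascii("uV", 8), nch), collapse = ""),
    paste(rep(pad_ascii(fmt_edf_num(pmin), 8), nch), collapse = ""),
    paste(rep(pad_ascii(fmt_edf_num(pmax), 8), nch), collapse = ""),
    paste(rep(pad_ascii(dmin, 8), nch), collapse = ""),
    paste(rep(pad_ascii(dmax, 8), nch), collapse = ""),
    paste(rep(pad_ascii("", 80), nch), collapse = ""),
    paste(rep(pad_ascii(spr, 8), nch), collapse = ""),
    paste(rep(pad_ascii("", 32), nch), collapse = "")
  )
  writeChar(paste0(hdr, sig), con, eos = NULL)
  # record-major interleaving: record, then signal, then sample
  A <- array(dig, c(nch, spr, n_rec))
  writeBin(as.integer(aperm(A, c(2, 1, 3))), con, size = 2L, endian = "little")
  invisible(path)
}

read_ascii <- function(con, n) {
  s <- readChar(con, n, useBytes = TRUE)
  if (length(s) == 0L || nchar(s, type = "bytes") < n)
    stopf("unreadable EDF header: file truncated")
  trimws(s)
}

#' Read an EDF recording
#'
#' Applies the EDF physical scaling so the returned data are in the physical
#' units declared in the file (microvolts for files written by
#' [write_recording()]).  All signals must share one sampling rate.
#'
#' @param path EDF file path.
#' @return An [new_recording()] object.
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  version <- read_ascii(con, 8)
  if (version != "0") stopf("not an EDF file (version field '%s')", version)
  read_ascii(con, 80); read_ascii(con, 80)      # patient / recording id
  read_ascii(con, 8); read_ascii(con, 8)        # date / time
  hdr_bytes <- as.integer(read_ascii(con, 8))
  read_ascii(con, 44)
  n_rec <- as.integer(read_ascii(con, 8))
  rec_dur <- as.numeric(read_ascii(con, 8))
  nch <- as.integer(read_ascii(con, 4))
  if (is.na(nch) || nch < 1L || is.na(n_rec) || is.na(rec_dur))
    stopf("unreadable EDF header")
  fields <- function(w) vapply(seq_len(nch), function(i) read_ascii(con, w), "")
  labels <- fields(16); fields(80); fields(8)   # label, transducer, dim
  pmin <- as.numeric(fields(8)); pmax <- as.numeric(fields(8))
  dmin <- as.numeric(fields(8)); dmax <- as.numeric(fields(8))
  fields(80)
  spr <- as.integer(fields(8)); fields(32)
  if (any(is.na(c(pmin, pmax, dmin, dmax, spr))))
    stopf("unreadable EDF signal headers")
  if (hdr_bytes != 256 * (nch + 1))
    stopf("unreadable EDF header: inconsistent header size")
  if (length(unique(spr)) != 1L)
    stopf("unsupported input: signals with mixed sampling rates")
  spr <- spr[1]
  fs <- spr / rec_dur

  expect <- n_rec * nch * spr
  raw <- readBin(con, "integer", n = expect, size = 2L, endian = "little")
  if (length(raw) != expect) stopf("truncated EDF file: expected %d samples, found %d",
                                   expect, length(raw))
  A <- array(raw, c(spr, nch, n_rec))
  dig <- matrix(aperm(A, c(2, 1, 3)), nrow = nch)
  # per-signal physical scaling (vectors of length nch recycle along columns)
  X <- (dig - dmin) / (dmax - dmin) * (pmax - pmin) + pmin
  new_recording(X, fs, labels = labels)
}
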