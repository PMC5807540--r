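# Sleep-architecture metrics, NREM cycle detection and stage/cycle masks.

#' Score sleep architecture from a hypnogram
#'
#' Definitions: TST = minutes in N1/N2/N3/REM within the lights interval;
#' sleep onset = first non-wake epoch after lights-off; sleep latency =
#' onset - lights-off; WASO = wake minutes between onset and the final
#' awakening (trailing wake excluded); efficiency = 100 x TST / time in bed;
#' REM latency = first REM - onset; stage percentages are of TST.  First-cycle
#' figures come from [detect_cycles()]; its N1/N2/N3 percentages are reported
#' as percent of TST (`cyc1_denominator = "cycle"` switches to percent of
#' cycle duration).
#'
#' @param hyp a [hypnogram()].
#' @param cyc1_denominator `"tst"` or `"cycle"`.
#' @return One-row data frame of class `sleep_architecture` with columns
#'   `TST, WASO, SE, SL, REML, N1, N2, N3, REM, Cyc1, N1c1, N2c1, N3c1`
#'   (minutes, percent as appropriate).  Undefined latencies are `NA`.
#' @export
score_architecture <- function(hyp, cyc1_denominator = c("tst", "cycle")) {
  cyc1_denominator <- match.arg(cyc1_denominator)
  ep_min <- hyp$epoch_s / 60
  st <- hyp$stages
  n <- length(st)
  tib <- (hyp$lights_on - hyp$lights_off) / 60
  asleep <- st != "W"
  mins <- function(sel) sum(sel) * ep_min

  tst <- mins(asleep)
  if (tst == 0) {
    out <- data.frame(TST = 0, WASO = 0, SE = 0, SL = NA_real_,
                      REML = NA_real_, N1 = NA_real_, N2 = NA_real_,
                      N3 = NA_real_, REM = NA_real_, Cyc1 = NA_real_,
                      N1c1 = NA_real_, N2c1 = NA_real_, N3c1 = NA_real_)
    class(out) <- c("sleep_architecture", class(out))
    return(out)
  }
  onset <- which(asleep)[1]
  last_sleep <- max(which(asleep))
  sl <- ((onset - 1) * hyp$epoch_s - hyp$lights_off) / 60
  waso <- mins(st[onset:last_sleep] == "W")
  se <- 100 * tst / tib
  first_rem <- which(st == "REM")[1]
  reml <- if (is.na(first_rem)) NA_real_ else (first_rem - onset) * ep_min
  pct <- function(s) 100 * mins(st == s) / tst

  cyc <- detect_cycles(hyp)
  c1 <- cyc[1, ]
  c1_idx <- seq(c1$start_epoch, c1$end_epoch)
  c1_dur <- length(c1_idx) * ep_min
  den <- if (cyc1_denominator == "tst") tst else c1_dur
  pct1 <- function(s) 100 * mins(st[c1_idx] == s) / den

  out <- data.frame(TST = tst, WASO = waso, SE = se, SL = sl, REML = reml,
                    N1 = pct("N1"), N2 = pct("N2"), N3 = pct("N3"),
                    REM = pct("REM"), Cyc1 = c1_dur,
                    N1c1 = pct1("N1"), N2c1 = pct1("N2"), N3c1 = pct1("N3"))
  class(out) <- c("sleep_architecture", class(out))
  out
}

#' Detect NREM-REM sleep cycles
#'
#' Classical rule: a cycle is a NREM period of at least 15 min followed by a
#' REM period of at least 5 min; the minimum REM duration is waived for the
#' first cycle.  REM episodes separated by less than 15 min of non-REM are
#' merged.  A REM episode occurring before 15 min of NREM have accumulated
#' does not close a cycle.  Trailing sleep after the last REM episode (or all
#' sleep, if REM never occurs) forms an incomplete cycle.
#'
#' @param hyp a [hypnogram()].
#' @param min_nrem_min,min_rem_min rule thresholds in minutes.
#' @return Data frame with `index, start_epoch, end_epoch, complete`
#'   (1-based epoch indices, inclusive).
#' @export
detect_cycles <- function(hyp, min_nrem_min = 15, min_rem_min = 5) {
  st <- hyp$stages
  asleep <- which(st != "W")
  if (!length(asleep)) stopf("no sleep epochs: cannot detect cycles")
  onset <- asleep[1]
  last_sleep <- max(asleep)
  ep_min <- hyp$epoch_s / 60

  # REM episodes, merging across gaps < 15 min of non-REM
  r <- rle(st[onset:last_sleep] == "REM")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  epi <- data.frame(start = starts[r$values], end = ends[r$values])
  if (nrow(epi) > 1L) {
    merged <- epi[1, ]
    for (k in 2:nrow(epi)) {
      gap <- (epi$start[k] - merged$end[nrow(merged)] - 1L) * ep_min
      if (gap < min_nrem_min) merged$end[nrow(merged)] <- epi$end[k]
      else merged <- rbind(merged, epi[k, ])
    }
    epi <- merged
  }
  epi$start <- epi$start + onset - 1L
  epi$end <- epi$end + onset - 1L

  cycles <- list()
  cyc_start <- onset
  for (k in seq_len(nrow(epi))) {
    nrem_min <- sum(st[cyc_start:epi$start[k]] %in% c("N1", "N2", "N3")) * ep_min
    rem_min <- sum(st[epi$start[k]:epi$end[k]] == "REM") * ep_min
    if (nrem_min < min_nrem_min) next               # REM too early: not a boundary
    if (length(cycles) > 0L && rem_min < min_rem_min) next  # short REM (non-first)
    cycles[[length(cycles) + 1L]] <- data.frame(
      index = length(cycles) + 1L, start_epoch = cyc_start,
      end_epoch = epi$end[k], complete = TRUE)
    cyc_start <- epi$end[k] + 1L
  }
  if (cyc_start <= last_sleep || length(cycles) == 0L) {
    cycles[[length(cycles) + 1L]] <- data.frame(
      index = length(cycles) + 1L, start_epoch = min(cyc_start, last_sleep),
      end_epoch = last_sleep, complete = FALSE)
  }
  do.call(rbind, cycles)
}

#' Epoch mask for a stage/cycle/artifact selection
#'
#' Intersects (i) epochs in the requested stages, (ii) epochs of the
#' requested cycle, and (iii) artifact-retained epochs.  The result is a
#' channels x epochs logical matrix; without an artifact mask it has a single
#' row `".all"` that applies to every channel.
#'
#' @param hyp a [hypnogram()].
#' @param stages character vector of stages to keep.
#' @param cycle optional cycle index (into [detect_cycles()]).
#' @param artifact_mask optional [reject_artifacts()] mask.
#' @return `epoch_mask` logical matrix (`TRUE` = analyzed).
#' @export
stage_mask <- function(hyp, stages = c("N2", "N3"), cycle = NULL,
                       artifact_mask = NULL) {
  in_stage <- hyp$stages %in% stages
  if (!any(in_stage)) stopf("empty selection: no epochs in stages %s",
                            paste(stages, collapse = "/"))
  if (!is.null(cycle)) {
    cyc <- detect_cycles(hyp)
    if (cycle > nrow(cyc)) stopf("empty selection: cycle %d not present", cycle)
    sel <- seq(cyc$start_epoch[cycle], cyc$end_epoch[cycle])
    in_cycle <- seq_along(hyp$stages) %in% sel
    in_stage <- in_stage & in_cycle
    if (!any(in_stage)) stopf("empty selection: stages x cycle intersection empty")
  }
  if (is.null(artifact_mask)) {
    m <- matrix(in_stage, nrow = 1, dimnames = list(".all", NULL))
  } else {
    n_ep <- min(length(in_stage), ncol(artifact_mask))
    m <- artifact_mask[, seq_len(n_ep), drop = FALSE] &
      rep(in_stage[seq_len(n_ep)], each = nrow(artifact_mask))
    if (!any(m)) stopf("empty selection: all selected epochs artifact-rejected")
  }
  structure(m, class = c("epoch_mask", "matrix", "array"), epoch_s = hyp$epoch_s)
}

# expand a mask to given channel labels; ".all" row broadcasts
mask_for <- function(mask, labels) {
  if (is.null(mask)) stopf("mask is required")
  if (nrow(mask) == 1L && rownames(mask)[1] == ".all") {
    out <- matrix(rep(as.logical(mask), each = length(labels)),
                  nrow = length(labels), dimnames = list(labels, NULL))
    return(out)
  }
  miss <- setdiff(labels, rownames(mask))
  if (length(miss)) stopf("mask lacks channels: %s", paste(miss, collapse = ","))
  mask[labels, , drop = FALSE]
}

# retained minutes per channel
mask_minutes <- function(mask, labels) {
  m <- mask_for(mask, labels)
  rowSums(m) * (attr(mask, "epoch_s") %||% 30) / 60
}

#' Compare sleep architecture between two groups
#'
#' Per parameter: group means and standard errors, absolute difference
#' (A - B), relative difference as percent of the group-B mean, and an
#' unpaired pooled-variance t-test.
#'
#' @param arch_a,arch_b lists of [score_architecture()] rows (>= 2 each).
#' @return Data frame, one row per architecture parameter.
#' @export
compare_architecture <- function(arch_a, arch_b) {
  if (length(arch_a) < 2L || length(arch_b) < 2L)
    stopf("need at least 2 subjects per group")
  A <- do.call(rbind, lapply(arch_a, as.data.frame))
  B <- do.call(rbind, lapply(arch_b, as.data.frame))
  params <- names(A)
  rows <- lapply(params, function(p) {
    a <- A[[p]]; b <- B[[p]]
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    if (length(a) < 2L || length(b) < 2L)
      return(data.frame(parameter = p, mean_a = NA, se_a = NA, mean_b = NA,
                        se_b = NA, diff = NA, rel_diff_pct = NA, t = NA,
                        df = NA, p = NA))
    tt <- unpaired_t(a, b)
    data.frame(parameter = p,
               mean_a = mean(a), se_a = stats::sd(a) / sqrt(length(a)),
               mean_b = mean(b), se_b = stats::sd(b) / sqrt(length(b)),
               diff = mean(a) - mean(b),
               rel_diff_pct = 100 * (mean(a) - mean(b)) / mean(b),
               t = tt$t, df = tt$df, p = tt$p)
  })
  do.call(rbind, rows)
}

#' Published group summary of sleep architecture (reference values)
#'
#' Published group means and standard errors of standard sleep-architecture
#' parameters for 16 unaffected first-degree relatives of schizophrenia
#' probands and 16 matched healthy controls from an overnight high-density
#' EEG study.  Used for summary-statistic t-tests and arithmetic checks.
#'
#' @return Data frame with `parameter, mean_fdr, se_fdr, mean_hs, se_hs,
#'   n_fdr, n_hs`.
#' @export
architecture_reference <- function() {
  data.frame(
    parameter = c("TST", "WASO", "SE", "N1", "N2", "N3", "REM", "REML",
                  "Cyc1", "N1c1", "N2c1", "N3c1"),
    mean_fdr = c(274.3, 84.63, 75.80, 14.20, 51.75, 19.49, 14.55, 119.57,
                 131.18, 5.59, 18.35, 8.03),
    se_fdr = c(19.3, 10.4, 2.5, 2.7, 2.3, 1.4, 1.7, 14.8, 16.8, 1.4, 4.1, 1.2),
    mean_hs = c(368.1, 67.22, 84.56, 3.53, 49.37, 25.89, 21.21, 96.38,
                119.53, 1.19, 11.20, 11.84),
    se_hs = c(9.04, 8.1, 1.8, 0.6, 1.9, 2.1, 0.9, 9.1, 9.3, 0.2, 1.3, 1.9),
    n_fdr = 16L, n_hs = 16L)
}
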