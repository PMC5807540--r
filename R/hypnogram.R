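SLEEP_STAGES <- c("W", "N1", "N2", "N3", "REM")

#' Hypnogram: sleep stages in 30-s epochs
#'
#' Epoch `e` (1-based index) covers the half-open interval
#' `[30*(e-1), 30*e)` seconds from recording start.  Epochs that end before
#' lights-off are treated as wake.
#'
#' @param stages character vector of stage labels, one per epoch, each one of
#'   `W, N1, N2, N3, REM`.
#' @param lights_off,lights_on lights-out interval in seconds from recording
#'   start; defaults to the full epoch span.
#' @param epoch_s epoch length in seconds (30).
#' @return Object of class `hypnogram`.
#' @export
hypnogram <- function(stages, lights_off = 0,
                      lights_on = length(stages) * epoch_s, epoch_s = 30) {
  stages <- as.character(stages)
  if (length(stages) == 0L) stopf("hypnogram has no epochs")
  bad <- which(!stages %in% SLEEP_STAGES)
  if (length(bad))
    stopf("unknown stage label '%s' at epoch %d (allowed: %s)",
          stages[bad[1]], bad[1], paste(SLEEP_STAGES, collapse = ","))
  if (!(lights_off < lights_on)) stopf("lights_off must precede lights_on")
  # epochs fully before lights-off are wake by convention
  pre <- which(seq_along(stages) * epoch_s <= lights_off)
  stages[pre] <- "W"
  structure(list(stages = stages, epoch_s = epoch_s,
                 lights_off = lights_off, lights_on = lights_on),
            class = "hypnogram")
}

#' @export
print.hypnogram <- function(x, ...) {
  tab <- table(factor(x$stages, levels = SLEEP_STAGES))
  cat(sprintf("<hypnogram> %d epochs of %g s; lights %g-%g s\n  %s\n",
              length(x$stages), x$epoch_s, x$lights_off, x$lights_on,
              paste(names(tab), tab, sep = ":", collapse = " ")))
  invisible(x)
}

n_epochs <- function(hyp) length(hyp$stages)

#' Read a hypnogram CSV
#'
#' Format: optional metadata lines `#lights_off=<seconds>` and
#' `#lights_on=<seconds>`, then a header `epoch,stage` and one row per 30-s
#' epoch.
#'
#' @param path CSV file path.
#' @return A [hypnogram()].
#' @export
read_hypnogram <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  meta_l <- grep("^#", lines, value = TRUE)
  body <- grep("^#", lines, value = TRUE, invert = TRUE)
  if (length(body) < 2L) stopf("hypnogram parse error: no epoch rows in %s", path)
  meta <- list()
  for (m in meta_l) {
    kv <- strsplit(sub("^#", "", m), "=", fixed = TRUE)[[1]]
    if (length(kv) == 2L) meta[[trimws(kv[1])]] <- as.numeric(trimws(kv[2]))
  }
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        stringsAsFactors = FALSE)
  if (!all(c("epoch", "stage") %in% names(df)))
    stopf("hypnogram parse error: header must be 'epoch,stage'")
  st <- trimws(df$stage)
  bad <- which(!st %in% SLEEP_STAGES)
  if (length(bad))
    stopf("hypnogram parse error: unknown stage '%s' in row %d of %s",
          st[bad[1]], bad[1], path)
  hypnogram(st,
            lights_off = meta$lights_off %||% 0,
            lights_on = meta$lights_on %||% (length(st) * 30))
}

#' Write a hypnogram CSV
#' @param hyp a [hypnogram()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hypnogram <- function(hyp, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("#lights_off=%g", hyp$lights_off),
               sprintf("#lights_on=%g", hyp$lights_on),
               "epoch,stage",
               sprintf("%d,%s", seq_along(hyp$stages), hyp$stages)), con)
  invisible(path)
}
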