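# Long-format event table I/O.
# Schema: subject,channel,kind,start_s,end_s,feature,value — one row per
# event feature; rows of one event share (subject, channel, kind, start, end).

#' Convert a wide per-event data frame to the long event-table format
#'
#' @param events data frame with columns `channel`, `start_s`, `end_s` plus
#'   any numeric feature columns.
#' @param subject subject identifier.
#' @param kind event kind (e.g. `"spindle"`, `"slow_wave"`).
#' @return Long-format data frame.
#' @export
events_to_table <- function(events, subject, kind) {
  base <- c("channel", "start_s", "end_s")
  if (!all(base %in% names(events))) stopf("events need columns %s",
                                           paste(base, collapse = ","))
  feats <- setdiff(names(events), base)
  if (nrow(events) == 0L)
    return(data.frame(subject = character(), channel = character(),
                      kind = character(), start_s = numeric(),
                      end_s = numeric(), feature = character(),
                      value = numeric()))
  out <- do.call(rbind, lapply(feats, function(f)
    data.frame(subject = subject, channel = events$channel, kind = kind,
               start_s = events$start_s, end_s = events$end_s,
               feature = f, value = as.numeric(events[[f]]))))
  if (any(out$start_s >= out$end_s)) stopf("event start must precede end")
  out[order(out$start_s, out$channel), ]
}

#' Read / write an event table CSV
#' @param path CSV path.
#' @return Long-format data frame (see [events_to_table()]).
#' @export
read_event_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject", "channel", "kind", "start_s", "end_s", "feature", "value")
  if (!all(need %in% names(df))) stopf("event table missing columns")
  if (nrow(df) && any(df$start_s >= df$end_s)) stopf("event start must precede end")
  df
}

#' @rdname read_event_table
#' @param tab long-format event table.
#' @export
write_event_table <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Reshape a long event table back to one row per event
#' @param tab long-format event table.
#' @return Wide data frame with one column per feature.
#' @export
table_to_events <- function(tab) {
  if (nrow(tab) == 0L)
    return(data.frame(channel = character(), start_s = numeric(),
                      end_s = numeric()))
  key <- interaction(tab$subject, tab$channel, tab$kind, tab$start_s,
                     tab$end_s, drop = TRUE)
  first <- !duplicated(key)
  wide <- tab[first, c("subject", "channel", "kind", "start_s", "end_s")]
  for (f in unique(tab$feature)) {
    sel <- tab$feature == f
    wide[[f]] <- tab$value[sel][match(key[first], key[sel])]
  }
  rownames(wide) <- NULL
  wide
}
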