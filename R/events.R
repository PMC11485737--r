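#' Open a JSONL event log
#'
#' Append-only log of analysis records, each line
#' `{"time_s": ..., "kind": ..., "payload": {...}}`. Timestamps are stream
#' time (frame index / frame rate), so replay and live runs of the same
#' movie produce identical logs.
#'
#' @param path output `.jsonl` file (truncated).
#' @return an `event_log` handle.
#' @export
event_log_open <- function(path) {
  con <- file(path, "w")
  lg <- new.env(parent = emptyenv())
  lg$con <- con; lg$path <- path; lg$last_time <- -Inf
  lg$records <- list()
  class(lg) <- "event_log"
  lg
}

#' Append one record to an event log
#' @param log an [event_log_open()] handle.
#' @param time_s stream time of the completed computation.
#' @param kind record kind (`shift`, `traces`, `indicators`, `network`,
#'   `ranking`, `synchrony`, `rf_update`, `stimulation`, `warning`).
#' @param payload list payload.
#' @export
log_event <- function(log, time_s, kind, payload) {
  if (time_s < log$last_time)
    warning("event log timestamps must be non-decreasing")
  log$last_time <- time_s
  rec <- list(time_s = time_s, kind = kind, payload = payload)
  writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = 10,
                              null = "null"), log$con)
  log$records[[length(log$records) + 1L]] <- rec
  invisible(rec)
}

#' @export
#' @rdname event_log_open
#' @param log an open `event_log`.
event_log_close <- function(log) {
  close(log$con)
  invisible(log$path)
}

#' Read a JSONL event log back as a list of records
#' @param path `.jsonl` file.
#' @param kind optional filter on record kind.
#' @return list of records.
#' @export
read_event_log <- function(path, kind = NULL) {
  recs <- lapply(readLines(path), jsonlite::fromJSON, simplifyVector = TRUE)
  if (!is.null(kind)) recs <- Filter(function(r) r$kind == kind, recs)
  recs
}
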