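# Session container and plain-text storage: a session store is a directory
# of delimited-text matrices plus a JSON manifest.

#' A recording session
#'
#' @param x `Nc x T` numeric matrix (channels by time).
#' @param sampling_rate sampling rate in Hz.
#' @param id session identifier.
#' @param channels optional channel labels (length `Nc`).
#' @return Object of class `session_data`.
#' @export
session_data <- function(x, sampling_rate, id = "session",
                         channels = NULL) {
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop("session '", id, "' contains non-finite values")
  if (ncol(x) < 1L) stop("session '", id, "' has no samples")
  if (is.null(sampling_rate) || !is.finite(sampling_rate))
    stop("session '", id, "' is missing a sampling rate")
  if (is.null(channels)) channels <- paste0("ch", seq_len(nrow(x)))
  if (length(channels) != nrow(x))
    stop("channel labels do not match channel count")
  structure(list(id = id, x = x, sampling_rate = sampling_rate,
                 channels = channels),
            class = "session_data")
}

#' @export
print.session_data <- function(x, ...) {
  cat(sprintf("<session_data '%s': %d channels x %d samples @ %g Hz>\n",
              x$id, nrow(x$x), ncol(x$x), x$sampling_rate))
  invisible(x)
}

#' Write sessions to a plain-text store
#'
#' Creates `path/` containing one tab-delimited `Nc x T` matrix per session
#' and a `manifest.json` with ids, files, sampling rates and channel labels.
#'
#' @param sessions list of [session_data].
#' @param path directory to create.
#' @return `path`, invisibly.
#' @export
write_sessions <- function(sessions, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  entries <- list()
  for (s in sessions) {
    stopifnot(inherits(s, "session_data"))
    file <- paste0(s$id, ".tsv")
    utils::write.table(s$x, file.path(path, file), sep = "\t",
                       row.names = FALSE, col.names = FALSE)
    entries[[length(entries) + 1L]] <-
      list(id = s$id, file = file, sampling_rate = s$sampling_rate,
           channels = s$channels)
  }
  jsonlite::write_json(list(sessions = entries),
                       file.path(path, "manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read sessions from a plain-text store
#'
#' @param path directory written by [write_sessions].
#' @return List of [session_data]; all sessions must share a channel count.
#' @export
read_sessions <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json in ", path)
  man <- jsonlite::read_json(mf, simplifyVector = TRUE)$sessions
  out <- list()
  for (i in seq_len(nrow(man))) {
    f <- file.path(path, man$file[i])
    if (!file.exists(f)) stop("manifest names a missing file: ", man$file[i])
    rate <- man$sampling_rate[i]
    if (is.null(rate) || is.na(rate))
      stop("session '", man$id[i], "' is missing a sampling rate")
    rate <- as.numeric(rate)
    x <- as.matrix(utils::read.table(f, sep = "\t"))
    dimnames(x) <- NULL
    ch <- if (is.list(man$channels)) man$channels[[i]] else man$channels[i, ]
    out[[length(out) + 1L]] <- session_data(x, rate, id = man$id[i],
                                            channels = ch)
  }
  nchan <- vapply(out, function(s) nrow(s$x), integer(1))
  if (length(unique(nchan)) > 1L)
    stop("sessions have ragged channel counts: ",
         paste(unique(nchan), collapse = ", "))
  out
}

#' Write an event table
#'
#' CSV with header `onset_sample,condition`.
#'
#' @param events data frame with those columns.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  utils::write.csv(events[, c("onset_sample", "condition")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Read an event table
#'
#' @param path CSV file with header `onset_sample,condition`.
#' @return Data frame.
#' @export
read_events <- function(path) {
  ev <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("onset_sample", "condition") %in% names(ev)))
    stop("event table must have columns onset_sample, condition")
  ev
}
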